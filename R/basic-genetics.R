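#' Per-marker allele frequencies
#'
#' Counts both alleles of every non-missing genotype (homozygotes contribute
#' two copies) and returns relative frequencies per marker.
#'
#' @param gt A `genotype_tbl`.
#' @return A tibble with columns `marker`, `allele`, `count`, `freq`.
#'   Frequencies sum to 1 within each marker.
#' @export
allele_freq <- function(gt) {
  gt <- validate_genotype_tbl(gt)
  sp <- gt_split(gt)
  res <- lapply(seq_along(sp$markers), function(j) {
    al <- c(sp$a1[, j], sp$a2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0L) {
      stop("marker '", sp$markers[j], "' has no non-missing genotypes", call. = FALSE)
    }
    tab <- table(al)
    tibble::tibble(
      marker = sp$markers[j],
      allele = names(tab),
      count  = as.integer(tab),
      freq   = as.numeric(tab) / length(al)
    )
  })
  dplyr::bind_rows(res)
}

#' Observed or Hardy-Weinberg-expected genotype frequencies
#'
#' Genotypes are unordered: `A|T` and `T|A` are the same category, labelled
#' with the sorted pair `"A/T"`. In expected mode the Hardy-Weinberg
#' probabilities are computed from [allele_freq()] of the same table:
#' \eqn{p_i^2} for homozygotes and \eqn{2 p_i p_j} for heterozygotes, over
#' all allele pairs with non-zero frequency.
#'
#' @param gt A `genotype_tbl`.
#' @param expected If `FALSE` (default), observed genotype counts; if
#'   `TRUE`, expected genotype probabilities under HWE.
#' @return A tibble with columns `marker`, `genotype`, and either `count`
#'   (observed) or `prob` (expected).
#' @export
genotype_freq <- function(gt, expected = FALSE) {
  gt <- validate_genotype_tbl(gt)
  if (!expected) {
    res <- lapply(gt_markers(gt), function(mk) {
      cell <- gt[[mk]]
      cell <- cell[!is.na(cell)]
      tab <- table(cell)
      tibble::tibble(marker = mk, genotype = names(tab), count = as.integer(tab))
    })
    return(dplyr::bind_rows(res))
  }
  freqs <- allele_freq(gt)
  hwe_genotype_probs(freqs)
}

# expected unordered genotype probabilities under HWE from an allele_freq table
hwe_genotype_probs <- function(freqs) {
  res <- lapply(split(freqs, freqs$marker), function(fm) {
    al <- fm$allele
    p <- fm$freq
    idx <- which(upper.tri(matrix(0, length(al), length(al)), diag = TRUE), arr.ind = TRUE)
    i <- idx[, "row"]; j <- idx[, "col"]
    prob <- as.numeric(ifelse(i == j, p[i]^2, 2 * p[i] * p[j]))
    lab <- vapply(seq_along(i), function(r) {
      paste(sort(c(al[i[r]], al[j[r]])), collapse = "/")
    }, character(1))
    tibble::tibble(marker = fm$marker[1], genotype = lab, prob = prob)
  })
  out <- dplyr::bind_rows(res)
  out[order(match(out$marker, unique(freqs$marker))), ]
}

#' Heterozygosity indicator matrix
#'
#' @param gt A `genotype_tbl`.
#' @return A tibble with `sample_id` and one integer column per marker:
#'   1 where the two allele labels differ, 0 where they are equal, `NA`
#'   where the genotype is missing.
#' @export
heterozygosity_matrix <- function(gt) {
  gt <- validate_genotype_tbl(gt)
  sp <- gt_split(gt)
  cols <- lapply(seq_along(sp$markers), function(j) {
    as.integer(sp$a1[, j] != sp$a2[, j])
  })
  names(cols) <- sp$markers
  tibble::tibble(sample_id = gt$sample_id, !!!cols)
}

#' Per-marker heterozygosity
#'
#' Either the observed average heterozygosity (column means of the 0/1
#' indicator matrix) or the expected heterozygosity under Hardy-Weinberg
#' equilibrium, \eqn{h_m = 1 - \sum_i p_i^2}.
#'
#' @param het A heterozygosity matrix from [heterozygosity_matrix()]
#'   (needed when `hwe = FALSE`; may be `NULL` otherwise).
#' @param freqs An allele-frequency table from [allele_freq()] (needed when
#'   `hwe = TRUE`; may be `NULL` otherwise).
#' @param hwe Use the HWE-expected form? Default `FALSE`.
#' @return A tibble with columns `marker`, `h`, `mode`.
#' @export
locus_heterozygosity <- function(het = NULL, freqs = NULL, hwe = FALSE) {
  if (hwe) {
    if (is.null(freqs)) stop("`freqs` is required when `hwe = TRUE`", call. = FALSE)
    if (!is.null(het)) {
      mk_h <- setdiff(names(het), "sample_id")
      if (!setequal(mk_h, unique(freqs$marker))) {
        stop("`het` and `freqs` cover different marker sets", call. = FALSE)
      }
    }
    out <- dplyr::summarise(
      dplyr::group_by(freqs, .data$marker),
      h = 1 - sum(.data$freq^2), .groups = "drop"
    )
    out <- out[match(unique(freqs$marker), out$marker), ]
    out$mode <- "hwe"
    return(out)
  }
  if (is.null(het)) stop("`het` is required when `hwe = FALSE`", call. = FALSE)
  markers <- setdiff(names(het), "sample_id")
  h <- vapply(markers, function(mk) {
    v <- het[[mk]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("marker '", mk, "' has no non-missing entries", call. = FALSE)
    }
    mean(v)
  }, numeric(1))
  tibble::tibble(marker = markers, h = unname(h), mode = "observed")
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium per marker
#'
#' Compares observed genotype counts with HWE-expected probabilities over
#' the union support per marker (categories absent on one side get a zero
#' count or their HWE probability). The statistic is
#' \eqn{X^2 = \sum (O - E)^2 / E} with \eqn{E = n p}. With
#' `simulate_p = TRUE` (the recommended mode for sparse multiallelic
#' tables) the p-value is Monte-Carlo: `B` tables are drawn multinomially
#' from the expected probabilities and
#' \eqn{p = (1 + \#\{X^2_{sim} \ge X^2_{obs}\}) / (B + 1)}. Otherwise the
#' asymptotic chi-square tail with `df = #categories - 1` is used.
#'
#' @param observed Observed genotype counts, as from
#'   `genotype_freq(gt, expected = FALSE)`.
#' @param expected Expected genotype probabilities, as from
#'   `genotype_freq(gt, expected = TRUE)`.
#' @param rescale Renormalize expected probabilities to sum to 1 on the
#'   union support (default `TRUE`). With `rescale = FALSE`, a category
#'   observed with zero expected probability is an error.
#' @param simulate_p Monte-Carlo p-value? Default `TRUE`.
#' @param B Number of simulated tables per marker (default 2000).
#' @param seed Optional integer seed; the test is deterministic given it.
#' @return A tibble with columns `marker`, `statistic`, `df`, `p_value`,
#'   `n`, `method`.
#' @export
hwe_test <- function(observed, expected, rescale = TRUE, simulate_p = TRUE,
                     B = 2000, seed = NULL) {
  stopifnot(all(c("marker", "genotype", "count") %in% names(observed)),
            all(c("marker", "genotype", "prob") %in% names(expected)))
  if (simulate_p && B < 1) stop("`B` must be >= 1 when `simulate_p = TRUE`", call. = FALSE)
  run <- function() {
    markers <- unique(observed$marker)
    res <- lapply(markers, function(mk) {
      obs <- observed[observed$marker == mk, ]
      exp <- expected[expected$marker == mk, ]
      support <- union(obs$genotype, exp$genotype)
      o <- obs$count[match(support, obs$genotype)]
      o[is.na(o)] <- 0L
      p <- exp$prob[match(support, exp$genotype)]
      p[is.na(p)] <- 0
      if (!rescale && any(p == 0 & o > 0)) {
        stop("marker '", mk, "': observed category with zero expected ",
             "probability (use `rescale = TRUE`)", call. = FALSE)
      }
      if (rescale) p <- p / sum(p)
      keep <- p > 0
      o <- o[keep]; p <- p[keep]
      n <- sum(o)
      e <- n * p
      x2 <- sum((o - e)^2 / e)
      df <- length(p) - 1L
      if (simulate_p) {
        sims <- stats::rmultinom(B, n, p)
        x2_sim <- colSums((sims - e)^2 / e)
        pv <- (1 + sum(x2_sim >= x2)) / (B + 1)
        method <- "HWE chi-square (Monte-Carlo p)"
      } else {
        pv <- stats::pchisq(x2, df = df, lower.tail = FALSE)
        method <- "HWE chi-square (asymptotic p)"
      }
      tibble::tibble(marker = mk, statistic = x2, df = df, p_value = pv,
                     n = n, method = method)
    })
    dplyr::bind_rows(res)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
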
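#' Draw a random marker model
#'
#' Marker models drive the synthetic-panel generator. A SNP gets two
#' nucleotide alleles with a minor-allele frequency drawn uniformly from
#' `maf_range`; an STR gets a uniform-random number of repeat alleles in
#' `k_range` with frequencies drawn from a flat Dirichlet, rejected until
#' the expected heterozygosity \eqn{1 - \sum p_i^2} reaches `min_het`
#' (microsatellites selected for panels are polymorphic by design).
#'
#' @param type `"SNP"` or `"STR"`.
#' @param k_range Integer range of STR allele counts (default 5:10).
#' @param maf_range SNP minor-allele-frequency range (default c(0.1, 0.5)).
#' @param min_het Minimum STR heterozygosity (default 0.5).
#' @return A `marker_model`: list with `type`, `alleles`, `freqs`.
#' @export
sample_marker_model <- function(type = c("SNP", "STR"), k_range = 5:10,
                                maf_range = c(0.1, 0.5), min_het = 0.5) {
  type <- match.arg(type)
  if (type == "SNP") {
    maf <- stats::runif(1, maf_range[1], maf_range[2])
    alleles <- sample(c("A", "C", "G", "T"), 2)
    freqs <- c(1 - maf, maf)
  } else {
    k <- if (length(k_range) == 1L) k_range else sample(k_range, 1)
    repeat {
      g <- stats::rgamma(k, 1)
      freqs <- g / sum(g)
      if (1 - sum(freqs^2) >= min_het) break
    }
    alleles <- as.character(seq(8, length.out = k))
  }
  structure(list(type = type, alleles = alleles, freqs = freqs),
            class = "marker_model")
}

# one i.i.d. HWE genotype column (two allele draws per individual)
draw_hwe_column <- function(model, n) {
  list(a1 = sample(model$alleles, n, replace = TRUE, prob = model$freqs),
       a2 = sample(model$alleles, n, replace = TRUE, prob = model$freqs))
}

#' Simulate a panel of mutually independent loci under HWE
#'
#' Each locus independently draws the two alleles of every individual
#' i.i.d. from its frequency model, so loci are in Hardy-Weinberg
#' equilibrium and mutually independent.
#'
#' @param models List of `marker_model`s (see [sample_marker_model()]).
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A `genotype_tbl`.
#' @export
simulate_unlinked <- function(models, n, seed = NULL) {
  run <- function() {
    cols <- lapply(models, draw_hwe_column, n = n)
    split_from_cols(cols, models, n)
  }
  sp <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  gt_from_split(sp, marker_types = vapply(models, `[[`, character(1), "type"))
}

#' Simulate a block of strongly linked loci
#'
#' A latent-haplotype model: `n_hap_classes` haplotype classes receive flat
#' Dirichlet frequencies; every individual draws two class indices i.i.d.
#' (so each locus marginally satisfies HWE), and each locus in the block
#' carries a fixed random map from class to allele (SNP: a random balanced
#' two-way partition of the classes; STR: a random surjection onto its
#' alleles, or a random injective choice of alleles when it has more
#' alleles than there are classes). All loci in the block are deterministic
#' functions of the same latent pair, which produces strong
#' linkage disequilibrium throughout the block.
#'
#' @param models List of >= 2 `marker_model`s forming the block.
#' @param n Number of individuals.
#' @param n_hap_classes Number of latent haplotype classes (default 6).
#' @param seed Optional integer seed.
#' @return A `genotype_tbl` holding just the block's columns.
#' @export
simulate_linked_block <- function(models, n, n_hap_classes = 6, seed = NULL) {
  if (length(models) < 2L) stop("a linked block needs at least 2 loci", call. = FALSE)
  run <- function() linked_block_cols(models, n, n_hap_classes)
  cols <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  sp <- split_from_cols(cols, models, n)
  gt_from_split(sp, marker_types = vapply(models, `[[`, character(1), "type"))
}

linked_block_cols <- function(models, n, n_hap_classes = 6) {
  if (n_hap_classes < 2L) stop("need at least 2 haplotype classes", call. = FALSE)
  g <- stats::rgamma(n_hap_classes, 1)
  q <- g / sum(g)
  c1 <- sample.int(n_hap_classes, n, replace = TRUE, prob = q)
  c2 <- sample.int(n_hap_classes, n, replace = TRUE, prob = q)
  lapply(models, function(model) {
    map <- class_allele_map(model, n_hap_classes)
    list(a1 = map[c1], a2 = map[c2])
  })
}

# fixed random class -> allele map for one locus of a linked block
class_allele_map <- function(model, C) {
  k <- length(model$alleles)
  if (model$type == "SNP") {
    half <- sample.int(C, C %/% 2L)
    map <- rep(model$alleles[1], C)
    map[half] <- model$alleles[2]
  } else if (k <= C) {
    map <- character(C)
    anchor <- sample.int(C, k)        # each allele reached by >= 1 class
    map[anchor] <- model$alleles
    rest <- setdiff(seq_len(C), anchor)
    map[rest] <- sample(model$alleles, length(rest), replace = TRUE)
  } else {
    map <- sample(model$alleles, C)   # injective: C distinct alleles
  }
  map
}

split_from_cols <- function(cols, models, n) {
  m <- length(cols)
  a1 <- matrix(NA_character_, n, m)
  a2 <- a1
  for (j in seq_len(m)) {
    a1[, j] <- cols[[j]]$a1
    a2[, j] <- cols[[j]]$a2
  }
  types <- vapply(models, `[[`, character(1), "type")
  markers <- paste0(types, ave(seq_len(m), types, FUN = seq_along))
  colnames(a1) <- colnames(a2) <- markers
  list(a1 = a1, a2 = a2, markers = markers,
       sample_id = paste0("ind", seq_len(n)), types = types)
}

#' Specify a simulated panel design
#'
#' Encodes the power-study design grid: a panel of `size` markers (half
#' SNPs, half STRs) in which `linkage` sets how many markers sit in the
#' single linked block and `bias` sets which marker type carries them.
#' Linkage levels map to linked-marker counts as: Unlinked 0, OnePair 2,
#' HalfQuarter `size/8`, Quarter `size/4`, Half `size/2`, ThreeQuarter
#' `3*size/4`, Almost `size - 2`, Fully `size`. With bias `"Both"` the
#' linked markers split equally between SNPs and STRs; with `"SNP"`
#' (`"STR"`) the linked markers are all of the biased type up to the
#' available `size/2`, the remainder spilling onto the other type.
#'
#' @param size Even panel size (number of markers).
#' @param linkage Linkage level label (see Details).
#' @param bias `"SNP"`, `"STR"` or `"Both"`.
#' @return A `panel_design`: list with `panel_size`, `n_linked`,
#'   `n_linked_snps`, `n_linked_strs`, `linkage`, `bias`.
#' @export
panel_design <- function(size,
                         linkage = c("Unlinked", "OnePair", "HalfQuarter", "Quarter",
                                     "Half", "ThreeQuarter", "Almost", "Fully"),
                         bias = c("Both", "SNP", "STR")) {
  linkage <- match.arg(linkage)
  bias <- match.arg(bias)
  if (size < 2 || size %% 2 != 0) {
    stop("`size` must be an even number >= 2 (half SNPs, half STRs)", call. = FALSE)
  }
  frac <- c(Unlinked = 0, HalfQuarter = 1 / 8, Quarter = 1 / 4, Half = 1 / 2,
            ThreeQuarter = 3 / 4, Fully = 1)
  n_linked <- switch(linkage,
                     OnePair = 2,
                     Almost = size - 2,
                     size * frac[[linkage]])
  if (n_linked != round(n_linked)) {
    stop("linkage level '", linkage, "' needs size divisible by ",
         1 / frac[[linkage]], call. = FALSE)
  }
  n_linked <- as.integer(n_linked)
  half <- size %/% 2L
  if (linkage %in% c("Unlinked", "Fully") && bias != "Both") {
    stop("linkage '", linkage, "' is only defined with bias = 'Both' ",
         "(no or all markers linked)", call. = FALSE)
  }
  if (bias == "Both") {
    if (n_linked %% 2L != 0L) {
      stop("bias 'Both' needs an even number of linked markers", call. = FALSE)
    }
    n_snp <- n_linked %/% 2L
    n_str <- n_linked %/% 2L
  } else if (bias == "SNP") {
    n_snp <- min(n_linked, half)
    n_str <- n_linked - n_snp
  } else {
    n_str <- min(n_linked, half)
    n_snp <- n_linked - n_str
  }
  if (n_snp > half || n_str > half) {
    stop("design asks for more linked markers of one type than the panel holds",
         call. = FALSE)
  }
  structure(list(panel_size = as.integer(size), n_linked = n_linked,
                 n_linked_snps = as.integer(n_snp), n_linked_strs = as.integer(n_str),
                 linkage = linkage, bias = bias),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("# Panel design: ", x$panel_size, " markers (",
      x$panel_size %/% 2, " SNPs / ", x$panel_size %/% 2, " STRs), ",
      x$linkage, " (", x$n_linked, " linked: ", x$n_linked_snps, " SNP + ",
      x$n_linked_strs, " STR), bias = ", x$bias, "\n", sep = "")
  invisible(x)
}

# fast internal generator: allele matrices for one panel realisation
panel_split <- function(design, n, n_hap_classes = 6) {
  half <- design$panel_size %/% 2L
  mk_models <- function(type, k) {
    lapply(seq_len(k), function(i) sample_marker_model(type))
  }
  linked <- c(mk_models("SNP", design$n_linked_snps),
              mk_models("STR", design$n_linked_strs))
  unlinked <- c(mk_models("SNP", half - design$n_linked_snps),
                mk_models("STR", half - design$n_linked_strs))
  cols <- c(if (length(linked) > 0)
              linked_block_cols(linked, n, n_hap_classes),
            lapply(unlinked, draw_hwe_column, n = n))
  models <- c(linked, unlinked)
  ord <- sample.int(length(models))
  split_from_cols(cols[ord], models[ord], n)
}

#' Build one synthetic panel from a design
#'
#' Places the design's linked SNP/STR markers in a single latent-haplotype
#' block, draws all remaining markers as independent HWE loci, and
#' randomizes the column order.
#'
#' @param design A [panel_design()].
#' @param n Number of individuals.
#' @param seed Optional integer seed; the panel is deterministic given it.
#' @param n_hap_classes Latent haplotype classes of the linked block
#'   (default 6).
#' @return A `genotype_tbl` with a `marker_type` attribute.
#' @export
build_panel <- function(design, n, seed = NULL, n_hap_classes = 6) {
  stopifnot(inherits(design, "panel_design"))
  run <- function() panel_split(design, n, n_hap_classes)
  sp <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  gt_from_split(sp, marker_types = sp$types)
}

# chi-square mutual-independence test on raw allele matrices; shared by
# test_independence (via the tidy wrappers) and the power study fast path
indep_core <- function(a1, a2, B, alpha = 0.05, statistics = c("K", "X"),
                       share_mode = "expected", min_expected = 5) {
  m <- ncol(a1)
  freq_list <- lapply(seq_len(m), function(j) {
    tab <- table(c(a1[, j], a2[, j]))
    as.numeric(tab) / sum(tab)
  })
  out <- list()
  if ("K" %in% statistics) {
    h <- vapply(freq_list, function(p) 1 - sum(p^2), numeric(1))
    k <- rowSums(a1 != a2)
    n <- length(k)
    pmf <- expected_K_distribution(h)
    counts <- tabulate(k + 1L, nbins = m + 1L)
    binning <- bin_support(pmf, n, min_expected)
    x2 <- chisq_statistic(counts, pmf, binning)
    null <- null_chisq_set(simulate_null_K(h, n, B), pmf, binning)
    out$K <- list(chisq = x2, p_value = 1 - null$ecdf(x2),
                  critical = critical_value(null, alpha))
  }
  if ("X" %in% statistics) {
    n <- nrow(a1)
    np <- n %/% 2L
    perm <- sample.int(n)
    pi <- perm[2L * seq_len(np) - 1L]
    pj <- perm[2L * seq_len(np)]
    s <- matrix(0L, np, m)
    for (j in seq_len(m)) {
      s[, j] <- ibs_count(a1[pi, j], a2[pi, j], a1[pj, j], a2[pj, j])
    }
    props <- if (share_mode == "expected") {
      do.call(rbind, lapply(freq_list, share_probs_enum))
    } else {
      t(apply(s, 2, function(v) tabulate(v + 1L, nbins = 3L) / np))
    }
    props <- tibble::tibble(p0 = props[, 1], p1 = props[, 2], p2 = props[, 3])
    pmf <- expected_X_distribution(props)
    counts <- tabulate(rowSums(s) + 1L, nbins = 2L * m + 1L)
    binning <- bin_support(pmf, np, min_expected)
    x2 <- chisq_statistic(counts, pmf, binning)
    null <- null_chisq_set(simulate_null_X(props, np, B), pmf, binning)
    out$X <- list(chisq = x2, p_value = 1 - null$ecdf(x2),
                  critical = critical_value(null, alpha))
  }
  out
}

#' Power study over a grid of panel designs
#'
#' For each design, simulates `trials` fresh panels and runs the
#' mutual-independence test for both summary statistics on each; the power
#' (or, for unlinked designs, the type-I error) is the fraction of trials
#' with p < `alpha`.
#'
#' @param designs A list of [panel_design()] objects (a single design is
#'   also accepted).
#' @param n Individuals per simulated panel (default 500).
#' @param trials Panels per design (default 1000).
#' @param B Null simulations per test (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed for the whole study.
#' @param statistics Which statistics to run (default both `"K"`, `"X"`).
#' @param n_hap_classes Latent classes of linked blocks (default 6).
#' @return A tibble with one row per design: `panel_size`, `n_linked`,
#'   `linkage`, `bias`, `power_K`, `power_X`, `trials`, `B`, `alpha`, `n`.
#' @export
power_study <- function(designs, n = 500, trials = 1000, B = 500, alpha = 0.05,
                        seed = NULL, statistics = c("K", "X"), n_hap_classes = 6) {
  if (inherits(designs, "panel_design")) designs <- list(designs)
  stopifnot(trials >= 1)
  run <- function() {
    purrr::map_dfr(designs, function(d) {
      rej <- matrix(FALSE, trials, length(statistics),
                    dimnames = list(NULL, statistics))
      for (t in seq_len(trials)) {
        sp <- panel_split(d, n, n_hap_classes)
        res <- indep_core(sp$a1, sp$a2, B = B, alpha = alpha,
                          statistics = statistics)
        for (st in statistics) rej[t, st] <- res[[st]]$p_value < alpha
      }
      row <- tibble::tibble(panel_size = d$panel_size, n_linked = d$n_linked,
                            linkage = d$linkage, bias = d$bias)
      for (st in statistics) row[[paste0("power_", st)]] <- mean(rej[, st])
      row$trials <- trials; row$B <- B; row$alpha <- alpha; row$n <- n
      row
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
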
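#' Number of identity-by-state shared alleles between two genotypes
#'
#' The size of the multiset intersection of the two diploid allele pairs:
#' identical genotypes share 2, genotypes with one allele label in common
#' share 1 (so `A/B` vs `B/B` shares 1), disjoint genotypes share 0.
#'
#' @param a,b Genotypes as `"x/y"` strings (vectorized; alleles in a cell
#'   may be in any order). `NA` in either argument yields `NA`.
#' @return Integer vector of 0, 1 or 2.
#' @export
shared_alleles <- function(a, b) {
  pa <- strsplit(as.character(a), "/", fixed = TRUE)
  pb <- strsplit(as.character(b), "/", fixed = TRUE)
  get <- function(p, k) vapply(p, function(x) if (length(x) == 2L) x[k] else NA_character_, character(1))
  ibs_count(get(pa, 1), get(pa, 2), get(pb, 1), get(pb, 2))
}

# vectorized multiset-intersection size for allele pairs (i,j) vs (u,v)
ibs_count <- function(i, j, u, v) {
  both_hom <- i == j & u == v
  a_hom <- i == j & u != v
  b_hom <- i != j & u == v
  raw <- (i == u) + (i == v) + (j == u) + (j == v)
  out <- ifelse(both_hom, 2L * (i == u),
         ifelse(a_hom, (i == u) + (i == v),
         ifelse(b_hom, (u == i) + (u == j), raw)))
  as.integer(out)
}

#' Randomly pair individuals
#'
#' Without replacement (the default everywhere): a uniform random
#' permutation of the individuals is split into `floor(n/2)` disjoint
#' consecutive pairs; with odd `n` one random individual is dropped. With
#' replacement: `n` pairs are drawn uniformly (with replacement) from all
#' unordered pairs of distinct individuals.
#'
#' @param n Number of individuals (>= 2).
#' @param replacement Sample pairs with replacement? Default `FALSE`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `pair`, `i`, `j` (indices into 1..n).
#' @export
pair_individuals <- function(n, replacement = FALSE, seed = NULL) {
  if (n < 2) stop("need at least 2 individuals to form pairs", call. = FALSE)
  run <- function() {
    if (!replacement) {
      perm <- sample.int(n)
      k <- n %/% 2L
      tibble::tibble(pair = seq_len(k),
                     i = perm[2 * seq_len(k) - 1L],
                     j = perm[2 * seq_len(k)])
    } else {
      i <- sample.int(n, n, replace = TRUE)
      j <- sample.int(n - 1L, n, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # j uniform on {1..n} \ {i}
      lo <- pmin(i, j)
      hi <- pmax(i, j)
      tibble::tibble(pair = seq_len(n), i = lo, j = hi)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' All unordered pairs of distinct individuals
#'
#' Exhaustive alternative to random pairing: all `choose(n, 2)` pairs.
#'
#' @param n Number of individuals (>= 2).
#' @return A tibble with columns `pair`, `i`, `j`.
#' @export
all_pairs <- function(n) {
  if (n < 2) stop("need at least 2 individuals to form pairs", call. = FALSE)
  cmb <- utils::combn(n, 2)
  tibble::tibble(pair = seq_len(ncol(cmb)), i = cmb[1, ], j = cmb[2, ])
}

#' Shared-allele counts for pairs of individuals across markers
#'
#' Forms pairs (see [pair_individuals()], or pass a pair list explicitly)
#' and counts identity-by-state shared alleles per pair per marker. A
#' missing genotype in either member of a pair gives a missing entry.
#'
#' @param gt A `genotype_tbl` with >= 2 individuals.
#' @param replacement Passed to [pair_individuals()].
#' @param seed Optional integer seed for the pairing.
#' @param pairs Optional tibble with columns `i`, `j` overriding the random
#'   pairing (e.g. [all_pairs()] output).
#' @return A tibble with columns `pair`, `i`, `j` and one integer column
#'   per marker with values in {0, 1, 2} (or `NA`).
#' @export
allele_share_matrix <- function(gt, replacement = FALSE, seed = NULL, pairs = NULL) {
  gt <- validate_genotype_tbl(gt)
  if (nrow(gt) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- pair_individuals(nrow(gt), replacement = replacement, seed = seed)
  }
  stopifnot(all(c("i", "j") %in% names(pairs)))
  sp <- gt_split(gt)
  cols <- lapply(seq_along(sp$markers), function(m) {
    ibs_count(sp$a1[pairs$i, m], sp$a2[pairs$i, m],
              sp$a1[pairs$j, m], sp$a2[pairs$j, m])
  })
  names(cols) <- sp$markers
  tibble::tibble(pair = seq_len(nrow(pairs)), i = pairs$i, j = pairs$j, !!!cols)
}

#' Observed proportions of sharing 0, 1 or 2 alleles per marker
#'
#' @param shares A shared-allele table from [allele_share_matrix()].
#' @return A tibble with columns `marker`, `p0`, `p1`, `p2`, `n_pairs`,
#'   `mode = "observed"`; `p0 + p1 + p2 = 1` per marker.
#' @export
observed_share_props <- function(shares) {
  markers <- setdiff(names(shares), c("pair", "i", "j"))
  res <- lapply(markers, function(mk) {
    v <- shares[[mk]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("marker '", mk, "' has no non-missing pairs", call. = FALSE)
    }
    cnt <- tabulate(v + 1L, nbins = 3L)
    tibble::tibble(marker = mk, p0 = cnt[1] / length(v), p1 = cnt[2] / length(v),
                   p2 = cnt[3] / length(v), n_pairs = length(v))
  })
  out <- dplyr::bind_rows(res)
  out$mode <- "observed"
  out
}

#' Expected sharing probabilities for unrelated individuals (IBS, HWE)
#'
#' For each marker, the probabilities that two unrelated individuals share
#' 0, 1 or 2 alleles identical by state, computed by enumerating all
#' unordered genotype pairs with Hardy-Weinberg probabilities
#' (\eqn{p_i^2}, \eqn{2 p_i p_j}) and accumulating the product of the two
#' independent genotype probabilities by shared-allele count.
#'
#' @param freqs An allele-frequency table from [allele_freq()].
#' @return A tibble with columns `marker`, `p0`, `p1`, `p2`,
#'   `mode = "expected"`.
#' @export
expected_share_props <- function(freqs) {
  res <- lapply(split(freqs, factor(freqs$marker, levels = unique(freqs$marker))),
                function(fm) {
    p <- share_probs_enum(fm$freq)
    tibble::tibble(marker = fm$marker[1], p0 = p[1], p1 = p[2], p2 = p[3])
  })
  out <- dplyr::bind_rows(res)
  out$mode <- "expected"
  out
}

# enumeration core: unordered genotype pairs under HWE for one allele
# frequency vector -> c(p0, p1, p2) of IBS sharing probabilities
share_probs_enum <- function(p) {
  k <- length(p)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  gi <- idx[, "row"]; gj <- idx[, "col"]        # genotype = alleles (gi, gj), gi <= gj
  gp <- ifelse(gi == gj, p[gi]^2, 2 * p[gi] * p[gj])
  ng <- length(gp)
  A <- rep(seq_len(ng), each = ng)              # ordered genotype pairs (A, B)
  B <- rep(seq_len(ng), times = ng)
  s <- ibs_count(gi[A], gj[A], gi[B], gj[B])
  w <- gp[A] * gp[B]
  vapply(0:2, function(kk) sum(w[s == kk]), numeric(1))
}
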
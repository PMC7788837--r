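#' Discrete distribution of a panel summary statistic
#'
#' Container for the distribution of K (number of heterozygous loci, support
#' 0..m) or X (number of shared alleles, support 0..2m). A tibble of
#' `value` / `prob` with attributes `statistic` ("K" or "X"), `type`
#' ("observed" or "expected"), and for observed distributions the count `n`
#' of complete-case units behind the frequencies.
#'
#' @param value Integer support 0..max.
#' @param prob Probabilities or relative frequencies summing to 1.
#' @param statistic `"K"` or `"X"`.
#' @param type `"observed"` or `"expected"`.
#' @param n Number of units (individuals or pairs) for observed mode.
#' @param counts Optional integer counts underlying observed frequencies.
#' @return A `discrete_dist` tibble.
#' @keywords internal
new_discrete_dist <- function(value, prob, statistic, type, n = NA_integer_,
                              counts = NULL) {
  stopifnot(length(value) == length(prob), all(prob >= -1e-12))
  if (abs(sum(prob) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  tbl <- tibble::tibble(value = as.integer(value), prob = as.numeric(prob))
  if (!is.null(counts)) tbl$count <- as.integer(counts)
  structure(tbl,
            class = c("discrete_dist", class(tibble::tibble())),
            statistic = statistic, type = type, n = n)
}

#' @export
print.discrete_dist <- function(x, ...) {
  cat("# ", attr(x, "type"), " distribution of ", attr(x, "statistic"),
      " (support 0..", max(x$value), ")\n", sep = "")
  NextMethod()
}

dist_statistic <- function(d) attr(d, "statistic")
dist_type <- function(d) attr(d, "type")
dist_n <- function(d) attr(d, "n")

#' Observed distribution of K, the number of heterozygous loci
#'
#' K per individual is the row sum of the heterozygosity indicator matrix.
#' Only complete-case individuals (no missing genotype at any marker) enter
#' the distribution, so the support stays 0..m; the number excluded is kept
#' in the `n_excluded` attribute.
#'
#' @param het A heterozygosity matrix from [heterozygosity_matrix()].
#' @return A `discrete_dist` with relative frequencies over 0..m.
#' @export
observed_K_distribution <- function(het) {
  markers <- setdiff(names(het), "sample_id")
  m <- length(markers)
  mat <- as.matrix(het[markers])
  complete <- stats::complete.cases(mat)
  if (!any(complete)) stop("no individual is complete for all markers", call. = FALSE)
  k <- rowSums(mat[complete, , drop = FALSE])
  counts <- tabulate(k + 1L, nbins = m + 1L)
  out <- new_discrete_dist(0:m, counts / sum(counts), "K", "observed",
                           n = sum(complete), counts = counts)
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Expected distribution of K under mutual independence
#'
#' The Poisson-binomial law of \eqn{K = \sum_m B(h_m)}: starting from
#' \eqn{P^0_{x=0} = 1}, each locus is folded in with
#' \deqn{P^m_{x=r} = P^{m-1}_{x=r} (1 - h_m) + P^{m-1}_{x=r-1} h_m,}
#' out-of-range terms contributing zero.
#'
#' @param h Per-marker heterozygosities: a numeric vector in \[0, 1\] or a
#'   tibble from [locus_heterozygosity()].
#' @return A `discrete_dist` over 0..m.
#' @export
expected_K_distribution <- function(h) {
  if (is.data.frame(h)) h <- h$h
  if (any(h < 0 | h > 1)) stop("heterozygosities must lie in [0, 1]", call. = FALSE)
  p <- 1
  for (hm in h) {
    p <- c(p, 0) * (1 - hm) + c(0, p) * hm
  }
  new_discrete_dist(0:length(h), p, "K", "expected")
}

#' Observed distribution of X, the number of shared alleles
#'
#' X per pair is the row sum of the shared-allele table; only pairs complete
#' for all markers are counted (support 0..2m).
#'
#' @param shares A shared-allele table from [allele_share_matrix()].
#' @return A `discrete_dist` with relative frequencies over 0..2m.
#' @export
observed_X_distribution <- function(shares) {
  markers <- setdiff(names(shares), c("pair", "i", "j"))
  m <- length(markers)
  mat <- as.matrix(shares[markers])
  complete <- stats::complete.cases(mat)
  if (!any(complete)) stop("no pair is complete for all markers", call. = FALSE)
  x <- rowSums(mat[complete, , drop = FALSE])
  counts <- tabulate(x + 1L, nbins = 2L * m + 1L)
  out <- new_discrete_dist(0:(2 * m), counts / sum(counts), "X", "observed",
                           n = sum(complete), counts = counts)
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Expected distribution of X under mutual independence
#'
#' Trinomial convolution over loci: with per-locus probabilities
#' \eqn{(p_0^m, p_1^m, p_2^m)} of sharing 0/1/2 alleles,
#' \deqn{P^m_{x=r} = P^{m-1}_{x=r} p_0^m + P^{m-1}_{x=r-1} p_1^m
#'       + P^{m-1}_{x=r-2} p_2^m,}
#' starting from \eqn{P^0_{x=0} = 1}. Either the Hardy-Weinberg expected
#' sharing probabilities ([expected_share_props()]) or the observed
#' proportions ([observed_share_props()]) may be supplied.
#'
#' @param props A share-probability table with columns `p0`, `p1`, `p2`.
#' @return A `discrete_dist` over 0..2m.
#' @export
expected_X_distribution <- function(props) {
  stopifnot(all(c("p0", "p1", "p2") %in% names(props)))
  p <- 1
  for (r in seq_len(nrow(props))) {
    p <- c(p, 0, 0) * props$p0[r] + c(0, p, 0) * props$p1[r] + c(0, 0, p) * props$p2[r]
  }
  new_discrete_dist(0:(2 * nrow(props)), p, "X", "expected")
}

#' Pair an observed and an expected distribution for plotting or per-unit
#' comparison
#'
#' With `transpose = FALSE`, a long tibble (`value`, `freq`, `origin`)
#' suitable for ggplot2. With `transpose = TRUE`, a per-unit tibble pairing
#' each observed K (or X) with a seeded draw from the expected
#' distribution; the row count equals the number of observed units.
#'
#' @param observed,expected `discrete_dist` objects with the same statistic
#'   and support.
#' @param transpose Per-unit layout? Default `FALSE`.
#' @param seed Optional seed for the expected draws when `transpose = TRUE`.
#' @return A tibble (see Details).
#' @export
compare_distributions <- function(observed, expected, transpose = FALSE, seed = NULL) {
  if (!identical(dist_statistic(observed), dist_statistic(expected))) {
    stop("distributions are for different statistics", call. = FALSE)
  }
  if (!identical(observed$value, expected$value)) {
    stop("distributions have different supports", call. = FALSE)
  }
  if (!transpose) {
    return(dplyr::bind_rows(
      tibble::tibble(value = observed$value, freq = observed$prob, origin = "observed"),
      tibble::tibble(value = expected$value, freq = expected$prob, origin = "expected")
    ))
  }
  if (!"count" %in% names(observed)) {
    stop("`observed` must carry counts for the per-unit layout", call. = FALSE)
  }
  obs_units <- rep(observed$value, observed$count)
  draw <- function() sample(expected$value, length(obs_units), replace = TRUE,
                            prob = expected$prob)
  exp_units <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stat <- dist_statistic(observed)
  out <- tibble::tibble(obs_units, exp_units)
  names(out) <- paste0(stat, c("_observed", "_expected"))
  out
}

#' @rdname compare_distributions
#' @param object A `discrete_dist`.
#' @param ... Unused.
#' @method autoplot discrete_dist
#' @export
autoplot.discrete_dist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = dist_statistic(object),
      y = if (dist_type(object) == "observed") "frequency" else "probability",
      title = paste(dist_type(object), "distribution of", dist_statistic(object))
    )
}

#' Plot an observed/expected distribution comparison
#'
#' @param observed,expected `discrete_dist` objects on the same support.
#' @return A ggplot object: observed frequencies as bars, expected
#'   probabilities as a line.
#' @export
plot_distribution_comparison <- function(observed, expected) {
  long <- compare_distributions(observed, expected, transpose = FALSE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$freq)) +
    ggplot2::geom_col(data = long[long$origin == "observed", ], fill = "grey60") +
    ggplot2::geom_line(data = long[long$origin == "expected", ], colour = "red") +
    ggplot2::labs(x = dist_statistic(observed), y = "frequency / probability")
}
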
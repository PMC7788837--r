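#' Bin a discrete support so every bin's expected count is at least 5
#'
#' Pearson's chi-square approximation needs adequate expected counts, so the
#' support of the expected distribution is partitioned into contiguous bins
#' with \eqn{n \sum p \ge} `min_expected` each. Bins are built by merging
#' from both tails inward toward the mode; any still-deficient bin is merged
#' with its neighbour on the mode side until the condition holds. The same
#' partition is applied to the observed counts and to every simulated null
#' replicate, which is what makes the simulated ECDF comparison valid.
#'
#' @param expected A `discrete_dist` (expected mode).
#' @param n Number of units the counts will come from.
#' @param min_expected Minimum expected count per bin (default 5).
#' @return A `support_binning`: a list with `assignment` (bin index for each
#'   support value), a `bins` tibble (`bin`, `from`, `to`, `prob`,
#'   `expected_n`), and the `n` / `min_expected` used.
#' @export
bin_support <- function(expected, n, min_expected = 5) {
  stopifnot(n >= 1)
  p <- expected$prob
  L <- length(p)
  if (max(p) >= 1 - 1e-12) {
    stop("degenerate distribution: no variation under the null", call. = FALSE)
  }
  if (n * sum(p) < 2 * min_expected) {
    stop("total expected count below ", 2 * min_expected,
         "; cannot form two valid bins", call. = FALSE)
  }
  e <- n * p
  mode_i <- which.max(e)
  # mark bin starts: greedy accumulation from each tail toward the mode
  brk <- rep(FALSE, L)
  brk[1] <- TRUE
  acc <- 0
  if (mode_i > 1L) {
    for (i in seq_len(mode_i - 1L)) {
      acc <- acc + e[i]
      if (acc >= min_expected) {
        brk[i + 1L] <- TRUE
        acc <- 0
      }
    }
  }
  if (mode_i < L) {
    acc <- 0
    for (i in L:(mode_i + 1L)) {
      acc <- acc + e[i]
      if (acc >= min_expected && i > mode_i + 1L) {
        brk[i] <- TRUE
        acc <- 0
      }
    }
    brk[mode_i + 1L] <- TRUE
  }
  assignment <- cumsum(brk)
  # fix-up: merge any deficient bin toward the mode until all bins pass
  repeat {
    eb <- tapply(e, assignment, sum)
    labs <- as.integer(names(eb))
    bad <- labs[eb < min_expected]
    if (length(bad) == 0L || length(labs) == 1L) break
    bmode <- assignment[mode_i]
    bb <- bad[1]
    target <- if (bb < bmode) bb + 1L else if (bb > bmode) bb - 1L else {
      # mode bin itself deficient: merge with its smaller neighbour
      nb <- c(bb - 1L, bb + 1L)
      nb <- nb[nb %in% labs]
      nb[which.min(eb[as.character(nb)])]
    }
    assignment[assignment == bb] <- target
    assignment <- match(assignment, sort(unique(assignment)))
  }
  eb <- tapply(e, assignment, sum)
  if (length(eb) < 2L) {
    stop("binning collapsed to a single bin; expected counts too small", call. = FALSE)
  }
  pb <- as.numeric(tapply(p, assignment, sum))
  bins <- tibble::tibble(
    bin = seq_along(pb),
    from = as.integer(tapply(expected$value, assignment, min)),
    to = as.integer(tapply(expected$value, assignment, max)),
    prob = pb,
    expected_n = n * pb
  )
  structure(list(assignment = assignment, bins = bins, n = n,
                 min_expected = min_expected, statistic = dist_statistic(expected)),
            class = "support_binning")
}

#' @export
print.support_binning <- function(x, ...) {
  cat("# Support binning for", x$statistic, "-", nrow(x$bins), "bins, n =", x$n, "\n")
  print(x$bins)
  invisible(x)
}

#' Pearson chi-square statistic over a binned support
#'
#' \eqn{X^2 = \sum_b (O_b - n p_b)^2 / (n p_b)} with the bins and `n` fixed
#' by the binning.
#'
#' @param counts Observed counts over the full support (summing to the
#'   binning's `n`).
#' @param expected The expected `discrete_dist` the binning was built from.
#' @param binning A `support_binning`.
#' @return The chi-square value (numeric scalar).
#' @export
chisq_statistic <- function(counts, expected, binning) {
  if (length(counts) != length(binning$assignment)) {
    stop("counts and binning cover different supports", call. = FALSE)
  }
  if (sum(counts) != binning$n) {
    stop("counts sum to ", sum(counts), " but the binning was built for n = ",
         binning$n, call. = FALSE)
  }
  ob <- as.numeric(tapply(counts, binning$assignment, sum))
  eb <- binning$bins$expected_n
  sum((ob - eb)^2 / eb)
}

#' Simulate null count vectors for K
#'
#' Under mutual independence each individual's K follows the exact
#' Poisson-binomial pmf of the per-locus heterozygosities, so the histogram
#' of `n` independent individuals is one Multinomial(n, pmf) draw. Each of
#' the `B` replicates is one such count vector over 0..m.
#'
#' @param h Per-marker heterozygosities (vector or [locus_heterozygosity()]
#'   tibble).
#' @param n Individuals per replicate.
#' @param B Number of replicates.
#' @param seed Optional integer seed.
#' @return A `B x (m+1)` integer matrix of counts; the expected pmf is kept
#'   in the `pmf` attribute.
#' @export
simulate_null_K <- function(h, n, B, seed = NULL) {
  stopifnot(n >= 1, B >= 1)
  pmf <- expected_K_distribution(h)
  run <- function() t(stats::rmultinom(B, n, pmf$prob))
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(sims) <- pmf$value
  attr(sims, "pmf") <- pmf
  sims
}

#' Simulate null count vectors for X
#'
#' The null X of one pair is the trinomial convolution of the per-locus
#' sharing probabilities; `n_pairs` independent pairs therefore give one
#' Multinomial(n_pairs, pmf) count vector over 0..2m per replicate.
#'
#' @param props Share-probability table (`p0`, `p1`, `p2` per marker).
#' @param n_pairs Pairs per replicate.
#' @param B Number of replicates.
#' @param seed Optional integer seed.
#' @return A `B x (2m+1)` integer matrix of counts with the pmf attached.
#' @export
simulate_null_X <- function(props, n_pairs, B, seed = NULL) {
  stopifnot(n_pairs >= 1, B >= 1)
  pmf <- expected_X_distribution(props)
  run <- function() t(stats::rmultinom(B, n_pairs, pmf$prob))
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(sims) <- pmf$value
  attr(sims, "pmf") <- pmf
  sims
}

#' Chi-square values of simulated null replicates
#'
#' Applies [chisq_statistic()] with one shared binning to every simulated
#' count vector and attaches the empirical CDF of the resulting values.
#'
#' @param sims Simulated count matrix from [simulate_null_K()] /
#'   [simulate_null_X()].
#' @param expected The expected `discrete_dist`.
#' @param binning The `support_binning` built from `expected` with the same
#'   `n` as the simulations.
#' @return A `chisq_null` object: list with `values`, `ecdf`, `binning`,
#'   `statistic`.
#' @export
null_chisq_set <- function(sims, expected, binning) {
  if (ncol(sims) != length(binning$assignment)) {
    stop("simulated support and binning differ", call. = FALSE)
  }
  ind <- outer(binning$assignment, seq_len(nrow(binning$bins)), `==`) + 0
  ob <- sims %*% ind                     # B x bins observed counts
  eb <- binning$bins$expected_n
  vals <- as.numeric(((ob - rep(eb, each = nrow(ob)))^2 %*% (1 / eb)))
  structure(list(values = vals, ecdf = stats::ecdf(vals), binning = binning,
                 statistic = binning$statistic),
            class = "chisq_null")
}

#' @export
print.chisq_null <- function(x, ...) {
  cat("# Simulated chi-square null for", x$statistic, "- B =", length(x$values),
      "\n  mean =", round(mean(x$values), 2),
      " 95% quantile =", round(critical_value(x), 2), "\n")
  invisible(x)
}

#' Empirical critical value of a simulated chi-square null
#'
#' The empirical `(1 - alpha)` quantile (type-1, i.e. an order statistic) of
#' the simulated null chi-square values.
#'
#' @param null A `chisq_null`.
#' @param alpha Significance level (default 0.05).
#' @return The critical chi-square value.
#' @export
critical_value <- function(null, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sorted <- sort(null$values)
  B <- length(sorted)
  idx <- min(B, max(1L, as.integer(ceiling((1 - alpha) * B - 1e-9))))
  sorted[idx]
}

#' Test a genotype panel for mutual independence
#'
#' End-to-end test of the null hypothesis that all markers of the panel are
#' mutually independent, using one of two summary statistics:
#' `statistic = "K"` compares the observed distribution of the number of
#' heterozygous loci per individual with its exact Poisson-binomial
#' expectation; `statistic = "X"` compares the distribution of
#' identity-by-state shared alleles over random disjoint pairs with its
#' trinomial-convolution expectation. Both are scored by a Pearson
#' chi-square over a binned support (expected count >= 5 per bin) and
#' referred to a simulated null: `B` replicate count vectors drawn under
#' independence, whose chi-square values give the empirical CDF from which
#' the p-value (`1 - ECDF(observed)`) and the critical value are read.
#'
#' @param gt A `genotype_tbl`.
#' @param statistic `"K"` or `"X"`.
#' @param B Number of null simulations (default 500; >= 100 recommended).
#' @param alpha Significance level (default 0.05).
#' @param share_mode For X: use `"expected"` (Hardy-Weinberg / unrelated,
#'   the default) or `"observed"` per-locus sharing probabilities.
#' @param seed Optional integer seed; the whole test (pairing and null
#'   simulation) is deterministic given it.
#' @param add_one Use the add-one Monte-Carlo p-value
#'   \eqn{(1 + \#\{null \ge obs\})/(B+1)} instead of the plain ECDF tail.
#' @param min_expected Minimum expected count per bin (default 5).
#' @return An `indep_test` object; see [tidy.indep_test()] /
#'   [glance.indep_test()].
#' @examples
#' gt <- build_panel(panel_design(10, "Unlinked", "Both"), n = 200, seed = 1)
#' fit <- test_independence(gt, statistic = "K", B = 200, seed = 1)
#' glance(fit)
#' @export
test_independence <- function(gt, statistic = c("K", "X"), B = 500, alpha = 0.05,
                              share_mode = c("expected", "observed"), seed = NULL,
                              add_one = FALSE, min_expected = 5) {
  statistic <- match.arg(statistic)
  share_mode <- match.arg(share_mode)
  gt <- validate_genotype_tbl(gt)
  run <- function() {
    if (statistic == "K") {
      freqs <- allele_freq(gt)
      h <- locus_heterozygosity(freqs = freqs, hwe = TRUE)
      het <- heterozygosity_matrix(gt)
      obs <- observed_K_distribution(het)
      expected <- expected_K_distribution(h)
      sims_fun <- function(n, B) simulate_null_K(h, n, B)
    } else {
      freqs <- allele_freq(gt)
      shares <- allele_share_matrix(gt, replacement = FALSE)
      props <- if (share_mode == "expected") {
        expected_share_props(freqs)
      } else {
        observed_share_props(shares)
      }
      obs <- observed_X_distribution(shares)
      expected <- expected_X_distribution(props)
      sims_fun <- function(n, B) simulate_null_X(props, n, B)
    }
    n <- dist_n(obs)
    binning <- bin_support(expected, n, min_expected = min_expected)
    x2 <- chisq_statistic(obs$count, expected, binning)
    null <- null_chisq_set(sims_fun(n, B), expected, binning)
    crit <- critical_value(null, alpha)
    p <- if (add_one) {
      (1 + sum(null$values >= x2)) / (B + 1)
    } else {
      1 - null$ecdf(x2)
    }
    structure(list(
      statistic = statistic, chisq = x2, critical = crit, p_value = p,
      reject = x2 > crit, alpha = alpha, B = B, n = n,
      observed = obs, expected = expected, binning = binning, null = null,
      share_mode = if (statistic == "X") share_mode else NA_character_,
      seed = seed
    ), class = "indep_test")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.indep_test <- function(x, ...) {
  cat("Mutual independence test (", x$statistic, ")\n", sep = "")
  cat("  chi-square = ", format(x$chisq, digits = 6),
      ", critical value (alpha = ", x$alpha, ") = ", format(x$critical, digits = 6),
      "\n  p-value = ", format(x$p_value, digits = 4),
      " -> ", if (x$reject) "reject" else "fail to reject",
      " mutual independence\n", sep = "")
  cat("  n = ", x$n, " ", if (x$statistic == "K") "individuals" else "pairs",
      ", B = ", x$B, " null simulations, ", nrow(x$binning$bins), " bins\n", sep = "")
  invisible(x)
}

#' Tidy an independence test
#'
#' @param x An `indep_test`.
#' @param ... Unused.
#' @return `tidy()`: one row per support bin with observed and expected
#'   counts. `glance()`: a one-row tibble with the test summary.
#' @method tidy indep_test
#' @export
tidy.indep_test <- function(x, ...) {
  ob <- as.numeric(tapply(x$observed$count, x$binning$assignment, sum))
  dplyr::mutate(x$binning$bins, observed_n = ob)
}

#' @rdname tidy.indep_test
#' @method glance indep_test
#' @export
glance.indep_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, chisq = x$chisq, critical = x$critical,
    p_value = x$p_value, reject = x$reject, alpha = x$alpha,
    n = x$n, B = x$B, n_bins = nrow(x$binning$bins)
  )
}

#' @rdname tidy.indep_test
#' @param object An `indep_test`.
#' @method autoplot indep_test
#' @export
autoplot.indep_test <- function(object, ...) {
  df <- tibble::tibble(chisq = object$null$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chisq)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = object$critical, colour = "red") +
    ggplot2::geom_vline(xintercept = object$chisq, colour = "blue") +
    ggplot2::labs(
      x = paste("chi-square for", object$statistic),
      y = "cumulative probability",
      title = "Simulated null ECDF (red: critical value, blue: observed)"
    )
}
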
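expected_from_probs <- function(p) {
  panelindep:::new_discrete_dist(seq_along(p) - 1L, p, "K", "expected")
}

test_that("support binning keeps every expected bin count at or above the floor", {
  b <- bin_support(expected_from_probs(c(0.5, 0.5)), n = 100)
  expect_equal(nrow(b$bins), 2L)
  expect_equal(b$assignment, c(1L, 2L))

  # thin tails are merged inward
  b2 <- bin_support(expected_from_probs(c(0.01, 0.49, 0.49, 0.01)), n = 100)
  expect_equal(b2$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(b2$bins$from, c(0L, 2L))
  expect_equal(b2$bins$to, c(1L, 3L))

  withr::with_seed(3, {
    for (rep in 1:20) {
      m <- sample(5:40, 1)
      h <- runif(m)
      n <- sample(30:2000, 1)
      d <- expected_K_distribution(h)
      if (n * (1 - max(d$prob)) < 10) next
      b <- bin_support(d, n)
      expect_true(all(b$bins$expected_n >= 5 - 1e-9))
      # bins are contiguous and cover the support
      expect_equal(b$assignment, sort(b$assignment))
      expect_equal(sum(b$bins$prob), 1, tolerance = 1e-9)
    }
  })
})

test_that("binning rejects degenerate and under-powered distributions", {
  expect_error(bin_support(expected_from_probs(c(0, 1)), n = 1000), "degenerate")
  expect_error(bin_support(expected_from_probs(c(0.5, 0.5)), n = 9), "two valid bins")
})

test_that("chi-square statistic over bins", {
  d <- expected_from_probs(c(0.5, 0.5))
  b <- bin_support(d, n = 100)
  expect_equal(chisq_statistic(c(50, 50), d, b), 0)
  expect_equal(chisq_statistic(c(60, 40), d, b), 4)
  expect_error(chisq_statistic(c(30, 30), d, b), "n = 100")
  expect_error(chisq_statistic(c(30, 30, 40), d, b), "supports")
})

test_that("null simulation: shapes, determinism and moments", {
  h <- c(0.2, 0.5, 0.7)
  sims <- simulate_null_K(h, n = 400, B = 50, seed = 1)
  expect_equal(dim(sims), c(50L, 4L))
  expect_equal(rowSums(sims), rep(400, 50), ignore_attr = TRUE)
  expect_identical(sims, simulate_null_K(h, 400, 50, seed = 1))
  # replicate mean of K near the Poisson-binomial mean
  kbar <- mean(sims %*% 0:3) / 400
  se <- sqrt(sum(h * (1 - h)) / (400 * 50))
  expect_lt(abs(kbar - sum(h)), 3 * se)

  props <- tibble::tibble(p0 = c(0.1, 0.3), p1 = c(0.4, 0.4), p2 = c(0.5, 0.3))
  simx <- simulate_null_X(props, n_pairs = 300, B = 40, seed = 2)
  expect_equal(dim(simx), c(40L, 5L))
  xbar <- mean(simx %*% 0:4) / 300
  expect_lt(abs(xbar - sum(props$p1 + 2 * props$p2)), 0.05)

  all2 <- tibble::tibble(p0 = c(0, 0), p1 = c(0, 0), p2 = c(1, 1))
  simall2 <- simulate_null_X(all2, n_pairs = 10, B = 5, seed = 3)
  expect_true(all(simall2[, "4"] == 10))

  h0 <- simulate_null_K(c(0, 0), n = 10, B = 5, seed = 4)
  expect_true(all(h0[, "0"] == 10))
})

test_that("null chi-square set behaves like a chi-square family", {
  withr::with_seed(12, {
    h <- runif(40, 0.2, 0.8)
    d <- expected_K_distribution(h)
    n <- 2000
    b <- bin_support(d, n)
    sims <- simulate_null_K(h, n, B = 400)
    null <- null_chisq_set(sims, d, b)
    expect_length(null$values, 400L)
    expect_true(all(null$values >= 0))
    # mean of the null set close to (bins - 1), the chi-square df heuristic
    expect_equal(mean(null$values), nrow(b$bins) - 1, tolerance = 0.15)
    # ECDF is a proper CDF
    expect_equal(null$ecdf(max(null$values)), 1)
    expect_equal(null$ecdf(-1), 0)

    # replicates equal to the expected counts give chi-square 0
    exact <- matrix(round(n * d$prob), 1)
    if (sum(exact) == n) {
      z <- null_chisq_set(exact, d, b)
      expect_lt(z$values, 1)
    }
  })
})

test_that("critical value is the empirical order-statistic quantile", {
  null <- structure(list(values = as.numeric(1:100)), class = "chisq_null")
  expect_equal(critical_value(null, alpha = 0.05), 95)
  expect_equal(critical_value(null, alpha = 0.99), 1)
  expect_equal(critical_value(null, alpha = 0.0001), 100)
  expect_error(critical_value(null, alpha = 0), "alpha")
})

test_that("independence test accepts independent panels and rejects duplicated markers", {
  gt <- build_panel(panel_design(20, "Unlinked", "Both"), n = 400, seed = 14)
  res <- test_independence(gt, "K", B = 300, seed = 2)
  expect_s3_class(res, "indep_test")
  expect_false(res$reject)

  # ten copies of the same marker: fully dependent panel
  base <- random_panel(500, 1, 0, seed = 15)
  cols <- stats::setNames(rep(list(base$SNP1), 10), paste0("m", 1:10))
  dup <- panelindep:::new_genotype_tbl(
    tibble::tibble(sample_id = base$sample_id, !!!cols))
  res2 <- test_independence(dup, "K", B = 300, seed = 3)
  expect_true(res2$reject)
  expect_lt(res2$p_value, 0.05)
})

test_that("p-value, decision and critical value are mutually consistent", {
  withr::with_seed(31, {
    for (rep in 1:12) {
      gt <- build_panel(panel_design(10, "Unlinked", "Both"), n = 300)
      res <- test_independence(gt, sample(c("K", "X"), 1), B = 200)
      if (res$p_value < res$alpha) expect_true(res$reject)
      if (res$p_value > res$alpha) expect_false(res$reject)
      expect_true(res$p_value >= 0 && res$p_value <= 1)
    }
  })
})

test_that("the whole test is bit-reproducible given a seed", {
  gt <- build_panel(panel_design(12, "Half", "Both"), n = 300, seed = 8)
  a <- test_independence(gt, "X", B = 150, seed = 10)
  b <- test_independence(gt, "X", B = 150, seed = 10)
  expect_identical(glance(a), glance(b))
  expect_identical(a$null$values, b$null$values)
  expect_identical(a$observed, b$observed)
})

test_that("X test runs in both share-probability modes", {
  gt <- build_panel(panel_design(10, "Unlinked", "Both"), n = 400, seed = 21)
  e <- test_independence(gt, "X", B = 200, seed = 5, share_mode = "expected")
  o <- test_independence(gt, "X", B = 200, seed = 5, share_mode = "observed")
  expect_false(e$reject)
  expect_false(o$reject)
  expect_false(identical(e$chisq, o$chisq))
  # add-one p-value never reaches exactly zero
  a <- test_independence(gt, "K", B = 100, seed = 6, add_one = TRUE)
  expect_gt(a$p_value, 0)
})

test_that("tidy and glance summarize the fitted test", {
  gt <- build_panel(panel_design(10, "Unlinked", "Both"), n = 300, seed = 22)
  res <- test_independence(gt, "K", B = 150, seed = 1)
  td <- tidy(res)
  expect_true(all(c("bin", "from", "to", "prob", "expected_n", "observed_n")
                  %in% names(td)))
  expect_equal(sum(td$observed_n), res$n)
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$chisq, res$chisq)
  p <- ggplot2::ggplot_build(autoplot(res))
  expect_s3_class(p, "ggplot_built")
})
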
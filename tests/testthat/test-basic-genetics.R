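test_that("allele frequencies match hand counts on the demonstration panel", {
  freqs <- allele_freq(toy_mixed_gt())
  str1 <- freqs[freqs$marker == "STR1", ]
  expect_equal(stats::setNames(str1$freq, str1$allele),
               toy_str1_freqs[order(names(toy_str1_freqs))])
  snp1 <- freqs[freqs$marker == "SNP1", ]
  expect_equal(stats::setNames(snp1$freq, snp1$allele), toy_snp1_freqs)
  # every non-missing cell contributes exactly two allele copies
  expect_equal(sum(str1$count), 20L)
})

test_that("allele counting handles missingness and degenerate loci", {
  df <- toy_mixed_df()
  df$STR1[c(1, 2)] <- NA
  freqs <- allele_freq(genotype_table(df, allele_sep = "|"))
  expect_equal(sum(freqs$count[freqs$marker == "STR1"]), 16L)
  expect_equal(sum(freqs$freq[freqs$marker == "STR1"]), 1, tolerance = 1e-12)

  hom <- genotype_table(tibble::tibble(id = 1:4, m = rep("A|A", 4)), "|")
  expect_equal(allele_freq(hom)$freq, 1)

  df$STR1 <- NA_character_
  expect_error(allele_freq(genotype_table(df, allele_sep = "|")), "STR1")
})

test_that("genotype frequencies pool unordered pairs and obey HWE in expected mode", {
  gt <- toy_mixed_gt()
  obs <- genotype_freq(gt)
  snp1 <- obs[obs$marker == "SNP1", ]
  expect_equal(stats::setNames(snp1$count, snp1$genotype), toy_snp1_geno_counts)

  exp <- genotype_freq(gt, expected = TRUE)
  snp1e <- exp[exp$marker == "SNP1", ]
  expect_equal(stats::setNames(snp1e$prob, snp1e$genotype),
               c(`A/A` = 0.25, `A/T` = 0.5, `T/T` = 0.25))
  sums <- as.numeric(tapply(exp$prob, exp$marker, sum))
  expect_equal(sums, rep(1, 2), tolerance = 1e-12)

  hom <- genotype_table(tibble::tibble(id = 1:4, m = rep("A|A", 4)), "|")
  expect_equal(genotype_freq(hom, expected = TRUE)$prob, 1)
})

test_that("heterozygosity matrix flags differing allele labels", {
  het <- heterozygosity_matrix(toy_mixed_gt())
  expect_equal(unname(unlist(het[1, c("STR1", "SNP1")])), c(0L, 0L))
  expect_equal(unname(unlist(het[2, c("STR1", "SNP1")])), c(1L, 0L))
  expect_equal(rowSums(het[-1]), toy_K, ignore_attr = TRUE)
})

test_that("locus heterozygosity: observed mean and HWE closed form", {
  gt <- toy_mixed_gt()
  het <- heterozygosity_matrix(gt)
  obs <- locus_heterozygosity(het = het)
  expect_equal(obs$h[obs$marker == "SNP1"], 0.6)
  expect_equal(obs$h[obs$marker == "STR1"], 0.6)

  freqs <- allele_freq(gt)
  hwe <- locus_heterozygosity(freqs = freqs, hwe = TRUE)
  expect_equal(hwe$h[hwe$marker == "SNP1"], 0.5)         # 1 - 2 * 0.25
  expect_equal(hwe$h[hwe$marker == "STR1"],
               1 - sum(toy_str1_freqs^2))
  # observed heterozygosity equals 1 - homozygote fraction
  obs_counts <- genotype_freq(gt)
  hom <- sum(obs_counts$count[obs_counts$marker == "SNP1" &
                                obs_counts$genotype %in% c("A/A", "T/T")])
  expect_equal(obs$h[obs$marker == "SNP1"], 1 - hom / 10)
})

test_that("observed and HWE heterozygosity agree for data simulated under HWE", {
  gt <- random_panel(1e5, 2, 1, seed = 31)
  freqs <- allele_freq(gt)
  h_obs <- locus_heterozygosity(het = heterozygosity_matrix(gt))
  h_hwe <- locus_heterozygosity(freqs = freqs, hwe = TRUE)
  expect_equal(h_obs$h, h_hwe$h, tolerance = 0.01)
})

test_that("HWE chi-square: perfect fit, zero-expected guard, Monte-Carlo runs", {
  observed <- tibble::tibble(marker = "m", genotype = c("A/A", "A/T", "T/T"),
                             count = c(25L, 50L, 25L))
  expected <- tibble::tibble(marker = "m", genotype = c("A/A", "A/T", "T/T"),
                             prob = c(0.25, 0.5, 0.25))
  fit <- hwe_test(observed, expected, simulate_p = FALSE)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
  expect_equal(fit$df, 2L)

  bad_exp <- tibble::tibble(marker = "m", genotype = c("A/A", "A/T"),
                            prob = c(0.5, 0.5))
  expect_error(hwe_test(observed, bad_exp, rescale = FALSE), "zero expected")
  ok <- hwe_test(observed, bad_exp, rescale = TRUE, simulate_p = TRUE,
                 B = 200, seed = 1)
  expect_true(ok$p_value >= 0 && ok$p_value <= 1)

  # full pipeline call on a mixed panel with the documented settings
  gt <- random_panel(120, 3, 2, seed = 8)
  res <- hwe_test(genotype_freq(gt), genotype_freq(gt, expected = TRUE),
                  rescale = TRUE, simulate_p = TRUE, B = 2000, seed = 2)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("Monte-Carlo HWE p-value matches the independent chi-square oracle", {
  gt <- random_panel(200, 2, 2, seed = 17)
  obs <- genotype_freq(gt)
  exp <- genotype_freq(gt, expected = TRUE)
  res <- hwe_test(obs, exp, simulate_p = TRUE, B = 20000, seed = 5)
  for (mk in res$marker) {
    o <- obs[obs$marker == mk, ]
    e <- exp[exp$marker == mk, ]
    support <- union(o$genotype, e$genotype)
    oc <- o$count[match(support, o$genotype)]; oc[is.na(oc)] <- 0L
    pp <- e$prob[match(support, e$genotype)]; pp[is.na(pp)] <- 0
    ref <- suppressWarnings(
      stats::chisq.test(oc, p = pp / sum(pp), simulate.p.value = TRUE, B = 20000)
    )
    expect_equal(res$statistic[res$marker == mk], unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(res$p_value[res$marker == mk], ref$p.value, tolerance = 0.02)
  }
})

test_that("Monte-Carlo HWE p-value matches exhaustive multinomial enumeration", {
  # all multinomial outcomes for n = 8 over 3 categories
  p <- c(0.5, 0.3, 0.2)
  n <- 8L
  obs <- c(5L, 0L, 3L)
  e <- n * p
  x2_obs <- sum((obs - e)^2 / e)
  outcomes <- expand.grid(o1 = 0:n, o2 = 0:n)
  outcomes <- outcomes[outcomes$o1 + outcomes$o2 <= n, ]
  outcomes$o3 <- n - outcomes$o1 - outcomes$o2
  x2_all <- apply(outcomes, 1, function(o) sum((o - e)^2 / e))
  prob_all <- apply(outcomes, 1, function(o) stats::dmultinom(o, prob = p))
  exact_p <- sum(prob_all[x2_all >= x2_obs - 1e-12])

  observed <- tibble::tibble(marker = "m", genotype = c("g1", "g2", "g3"), count = obs)
  expected <- tibble::tibble(marker = "m", genotype = c("g1", "g2", "g3"), prob = p)
  mc <- hwe_test(observed, expected, simulate_p = TRUE, B = 1e5, seed = 42)
  expect_lt(abs(mc$p_value - exact_p), 0.01)
})
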
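# Shared fixtures, built in code.

# 10-individual demonstration panel: one STR and one SNP column.
toy_mixed_df <- function() {
  tibble::tibble(
    sample_id = as.character(1:10),
    STR1 = c("12|12", "13|14", "13|13", "14|15", "15|13",
             "13|14", "14|3", "12|2", "14|14", "15|15"),
    SNP1 = c("A|A", "T|T", "A|T", "A|T", "T|A",
             "A|T", "A|A", "T|A", "T|T", "A|T")
  )
}

toy_mixed_gt <- function() genotype_table(toy_mixed_df(), allele_sep = "|")

# frozen hand counts for the toy panel
toy_str1_freqs <- c(`12` = 0.15, `13` = 0.25, `14` = 0.30, `15` = 0.20,
                    `2` = 0.05, `3` = 0.05)
toy_snp1_freqs <- c(A = 0.5, T = 0.5)
toy_snp1_geno_counts <- c(`A/A` = 2L, `A/T` = 6L, `T/T` = 2L)
toy_K <- c(0L, 1L, 1L, 2L, 2L, 2L, 1L, 2L, 0L, 1L)

# random independent HWE panel as a genotype_tbl (small, for IO round trips)
random_panel <- function(n, n_snp, n_str, seed) {
  withr::with_seed(seed, {
    models <- c(lapply(seq_len(n_snp), function(i) sample_marker_model("SNP")),
                lapply(seq_len(n_str), function(i) sample_marker_model("STR")))
    simulate_unlinked(models, n)
  })
}

# naive multiset-intersection oracle for shared-allele counting
naive_shared <- function(g1, g2) {
  shared <- 0L
  pool <- g2
  for (a in g1) {
    hit <- match(a, pool)
    if (!is.na(hit)) {
      shared <- shared + 1L
      pool <- pool[-hit]
    }
  }
  shared
}

# frequency table for a single marker in allele_freq() layout
freq_tbl <- function(p, marker = "m1") {
  tibble::tibble(marker = marker, allele = paste0("a", seq_along(p)),
                 count = NA_integer_, freq = p)
}
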
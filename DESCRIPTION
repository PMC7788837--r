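Package: panelindep
Title: Panel-Wide Independence Testing for Mixed-Marker Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests mutual (panel-wide) independence of multi-locus diploid
    genotype panels that mix marker types (SNPs, STRs, indels). Two summary
    statistics are compared against their exact expectations under
    independence: the number of heterozygous loci per individual (K, a
    Poisson-binomial count) and the number of identity-by-state shared
    alleles per pair of unrelated individuals (X, a trinomial convolution).
    Observed distributions are scored with a Pearson chi-square statistic
    whose null distribution is simulated, with critical values and p-values
    read off the empirical CDF. Includes per-marker allele and genotype
    frequencies, heterozygosity, Hardy-Weinberg testing with Monte-Carlo
    p-values, readers for tabular and VCF genotype files, and a synthetic
    mixed SNP/STR panel generator with a linked-block model for power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
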
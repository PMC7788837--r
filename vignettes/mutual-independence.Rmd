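---
title: "Testing mutual independence of mixed marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing mutual independence of mixed marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelindep)
```

## The problem

Marker panels used in forensic genetics, population genetics and disease
studies increasingly mix marker types: biallelic SNPs next to multiallelic
STRs and indels. Whether such a panel behaves as a set of *independent* loci
matters for every downstream probability calculation (match probabilities,
ancestry models, panel design). The classical check — pairwise linkage
disequilibrium (D′, r²) per pair of loci — scales poorly and by construction
misses higher-order dependence: a panel can be pairwise-equilibrium yet
jointly dependent through triplets, quartets, or the whole panel. *Mutual
independence* is the stronger null hypothesis that **no** subset of the
panel carries a non-random association.

`panelindep` tests that hypothesis globally with two summary statistics
whose exact distributions under the null are computable from per-locus
quantities alone:

* **K**, the number of heterozygous loci of one individual. If locus $m$
  has heterozygosity $h_m$ and loci are independent, $K = \sum_m K_m$ with
  $K_m \sim \mathrm{Bernoulli}(h_m)$, i.e. K is Poisson-binomial. The pmf
  is built by the forward recurrence
  $$P^m_{x=r} = P^{m-1}_{x=r}\,(1-h_m) + P^{m-1}_{x=r-1}\,h_m,$$
  starting from $P^0_{x=0}=1$: the $m$-th locus is either homozygous
  (leaving $r$ heterozygous loci among the first $m-1$) or heterozygous
  (leaving $r-1$).
* **X**, the number of alleles shared identical-by-state by a pair of
  individuals, summed over loci; each locus contributes $X_m \in
  \{0,1,2\}$, the multiset intersection of the two diploid genotypes. With
  per-locus sharing probabilities $(p_0^m, p_1^m, p_2^m)$ the null law of
  $X$ is the trinomial convolution
  $$P^m_{x=r} = P^{m-1}_{x=r}\,p_0^m + P^{m-1}_{x=r-1}\,p_1^m +
    P^{m-1}_{x=r-2}\,p_2^m.$$
  The $(p_0,p_1,p_2)$ come either from the Weir unrelated-pair expectations
  under Hardy-Weinberg equilibrium (enumerating all unordered genotype
  pairs with probabilities $p_i^2$ and $2p_ip_j$) or, for non-ideal
  samples, from the observed sharing proportions.

Both statistics collapse an $m$-locus panel into a single integer per
individual (or pair), so the comparison of observed and expected
distributions has a handful of degrees of freedom regardless of how many
loci — and which types of loci — the panel contains. That is what makes
the approach practical where a free-parameter-per-subset test is not.

## The test

The observed distribution of K (over individuals) or X (over
$\lfloor n/2\rfloor$ random disjoint pairs) is scored against its exact
expectation with a Pearson chi-square statistic. Two technicalities carry
the inferential weight:

**Binning.** The chi-square approximation needs adequate expected counts,
so the support is partitioned into contiguous bins with expected count
$n\sum p \ge 5$, merging greedily from both tails inward toward the mode
(`bin_support()`, `min_expected = 5`). Any bin still below the floor after
the tail passes is merged toward the mode. The identical partition is
applied to the observed counts and to every null replicate — without a
shared partition the simulated reference distribution would not be
comparable.

**Simulated null.** K and X are sums of *independent but non-identical*
per-locus trials, so the usual multinomial chi-square theory does not apply
directly. Instead the null distribution of the statistic is simulated:
`B` replicate count vectors are drawn under exact independence, each is
scored with the same binning, and the empirical CDF of the `B` chi-square
values supplies both the critical value (the empirical $(1-\alpha)$
quantile, an order statistic) and the p-value ($1-\mathrm{ECDF}$ at the
observed value; an add-one variant $(1+\#\{{\rm null}\ge{\rm obs}\})/(B+1)$
is available via `add_one = TRUE`).

A null replicate is drawn as **one multinomial sample** from the exact
pmf: under independence each individual's K is i.i.d. Poisson-binomial, so
the histogram of $n$ individuals is exactly $\mathrm{Multinomial}(n,
\mathrm{pmf})$ — and likewise for X with the trinomial-convolution pmf.
This is a distributional identity, not an approximation, and it is what
makes thousand-trial power studies cheap: no per-locus Bernoulli matrices
are ever materialised.

`test_independence()` wires the whole chain: allele frequencies →
heterozygosities or sharing probabilities → exact expected distribution →
binning → observed chi-square → simulated null → decision. Everything
downstream of the seed is deterministic, including the random pairing for
X.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `B` | 500 | null simulations; the p-value resolution is 1/B |
| `alpha` | 0.05 | significance level for the critical value |
| `min_expected` | 5 | expected-count floor per bin |
| `share_mode` | `"expected"` | Weir/HWE vs observed per-locus sharing probabilities |
| `replacement` | `FALSE` | pairing scheme for X (disjoint random pairs) |

The defaults mirror the analysis conditions the method was calibrated
under: B = 500 null replicates, $\alpha = 0.05$, disjoint pairing with
$\lfloor n/2 \rfloor$ pairs. With odd $n$ one random individual is dropped
from the pairing. `all_pairs()` exposes the exhaustive
$\binom{n}{2}$-pair alternative; note its pairs are heavily dependent, so
the X null (which assumes independent pairs) is calibrated only for the
disjoint scheme.

**Missing data.** A missing genotype at marker $j$ removes that individual
from marker $j$'s allele/genotype/heterozygosity counts, and removes any
pair containing it from marker $j$'s sharing counts. The distributions of
K and X are computed over complete cases only (individuals or pairs with
no missing genotype at any marker), which keeps the support fixed at
$0..m$ and $0..2m$; the number of exclusions is reported via the
`n_excluded` attribute.

## The synthetic-panel generator

`panel_design()` / `build_panel()` reproduce the power-study design grid:
panels of even size (half SNPs, half STRs) with a prescribed fraction of
linked markers (Unlinked, OnePair, HalfQuarter, Quarter, Half,
ThreeQuarter, Almost, Fully) carried by SNPs, STRs or both ("bias").

* **Unlinked loci** draw both alleles i.i.d. from the marker's frequency
  model — exact HWE, exact mutual independence. SNP minor-allele
  frequencies are uniform on $[0.1, 0.5]$ (the usual panel-design MAF
  filter); STRs get 5–10 alleles with flat-Dirichlet frequencies rejected
  until heterozygosity $\ge 0.5$ (panel STRs are polymorphic by design).
* **Linked loci** sit in a single block driven by a latent-haplotype
  model: 6 haplotype classes with flat-Dirichlet frequencies; each
  individual draws two class indices i.i.d.; each locus in the block maps
  classes to alleles through a fixed random map (balanced two-way
  partition for SNPs, random surjection for STRs). Every block locus is a
  deterministic function of the same latent pair, which produces strong
  LD across the whole block while each locus *marginally* stays in exact
  HWE (the class pair is drawn i.i.d.).

The generator emulates the two regimes the calibration depends on —
exact independence + HWE (type-I error) and strong inter-locus dependence
(power at high linkage). It deliberately does **not** emulate graded,
partial LD of recombining chromosomes: linked blocks are completely
linked. Consequently intermediate linkage levels are far easier to detect
here than in coalescent-simulated or real data — at $n = 500$ a
quarter-linked panel of 32 markers is already detected essentially always
— so power values at intermediate linkage characterize this generator,
not any empirical dataset, and comparisons across linkage levels are
qualitative (ordering saturates at 1). Passing type-I and full-linkage
checks therefore says the *test* is calibrated and consistent; it does not
certify power numbers for real chromosomal LD.

Default study conditions (used by the acceptance script and tests):
$n = 500$ individuals per simulated panel, 1000 trials for headline power
grids (scaled-down runs use 200–300 trials), B = 500 (scaled-down 200).
Simulation problem sizes in the test suite were chosen to keep each check
sharp but cheap: exhaustive enumerations at $m \le 10$ loci, Monte-Carlo
convergence checks at $10^5$–$10^6$ draws, power grids at 200–300 trials.

## Numerical and design choices

* The recurrences are iterative forward passes ($O(m^2)$ for K,
  $O(m \cdot 2m)$ for X) in double precision — exact and fast for panels
  up to thousands of loci; no normal or saddlepoint approximation is used.
* Allele labels are opaque strings ("A", "12", "9.3"); nothing is ever
  parsed numerically, so SNPs, STRs and indels mix freely. Genotypes are
  unordered; phase in VCF input is discarded.
* The allele separator of tabular files is matched literally
  (`allele_sep = "|"` needs no regex escaping).
* Hardy-Weinberg testing uses the Pearson statistic over the union
  genotype support with Monte-Carlo p-values by default (multinomial
  draws from the expected probabilities, add-one estimator); the
  asymptotic branch uses df = categories − 1, appropriate when expected
  probabilities are treated as fixed.
* Degenerate inputs fail loudly: monomorphic expected distributions
  ("no variation under the null"), all-missing markers, total expected
  count below two bins' worth.
* `critical_value()` is a type-1 (order-statistic) empirical quantile, so
  decisions are reproducible across platforms; `reject` is defined as
  observed chi-square exceeding the critical value, which can disagree
  with `p < alpha` only when the observed value ties a null order
  statistic exactly.
* The with-replacement pairing mode draws `n` pairs uniformly from all
  distinct-individual pairs (the description of this mode in prior art is
  ambiguous; the exhaustive reading is available separately as
  `all_pairs()`). All shipped analyses use the without-replacement
  default.
* Pairs are formed once per dataset, not re-randomized per marker, so a
  pair occupies one row across all markers of the share table.

## Worked example

```{r example, eval = FALSE}
library(panelindep)

# a mixed panel believed independent: 94 SNPs + 6 STRs, 2504 individuals
models <- c(lapply(1:94, function(i) sample_marker_model("SNP")),
            lapply(1:6, function(i) sample_marker_model("STR")))
gt <- simulate_unlinked(models, n = 2504, seed = 2020)

fit_K <- test_independence(gt, "K", B = 500, seed = 1)
fit_X <- test_independence(gt, "X", B = 500, seed = 1)
glance(fit_K)
glance(fit_X)
autoplot(fit_K)   # null ECDF with critical value and observed statistic
```

With independent input both tests fail to reject; duplicating a marker
ten times, or building the panel with `panel_design(size, "Fully",
"Both")`, drives the observed chi-square orders of magnitude past the
critical value.

## Limitations

* The test says *whether* the panel deviates from mutual independence,
  not *which* markers drive the deviation.
* Sharing expectations assume unrelated individuals; cryptic relatedness
  inflates X and will read as dependence.
* The X null treats pairs as independent, which holds for disjoint random
  pairs but not for the exhaustive all-pairs table.
* Complete-case filtering can discard many individuals in panels with
  scattered missingness; the exclusion counts are reported so users can
  judge.
* The generator's linked blocks are completely linked; graded r² levels
  between those extremes require an external simulator.
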
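---
title: "Distinguishing long-term sperm storage from facultative parthenogenesis in SNP-genotyped litters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing long-term sperm storage from facultative parthenogenesis in SNP-genotyped litters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirescan)
```

## The problem

A female snake kept in strict isolation gives birth. Two mechanisms can
explain the litter: **long-term sperm storage** (LTSS) — she was inseminated
before isolation and stored viable sperm, so the litter is ordinary sexual
offspring — or **facultative parthenogenesis** (FP) — she produced the
litter asexually by automixis. The two hypotheses make sharply different
genetic predictions, and with a SNP genotype matrix for the mother and her
offspring (typically from ddRAD sequencing) they can be separated
decisively:

* Under LTSS, offspring carry one maternal and one **paternal** allele at
  every locus. At loci where the mother is homozygous, any allele she does
  not carry must be paternal.
* Under automictic FP, every offspring allele is a copy of a maternal
  allele, and most automixis variants strip heterozygosity. In ZW taxa
  (snakes: females ZW, males ZZ, WW inviable) parthenogens are also
  exclusively male.

sirescan implements this comparison end to end: Structure-format genotype
I/O and locus filtering, the maternal-homozygosity paternal-allele scan, a
reproductive-mode classifier, a minimal sibship stage that bounds the
number of sires, a litter simulator used both for testing and for power
analysis, and an in-silico ddRAD digest utility for designing the assay
itself.

## The paternal-allele scan

Let $H$ be the set of loci at which the mother's genotype is homozygous
(missing maternal genotypes are excluded). For offspring $o$ and locus
$\ell \in H$ with maternal allele $a_\ell$, define

$$
f_{o\ell} = \mathbb{1}\!\left[\,g_{o\ell} \text{ is called and contains an
allele} \neq a_\ell\,\right].
$$

Three summaries are reported by `scan_paternal_alleles()`:

* the **per-offspring paternal fraction**
  $\hat p_o = \sum_\ell f_{o\ell} / \#\{\ell : g_{o\ell}\ \text{called}\}$;
* the **conservative count**: loci where *all* offspring are flagged.
  Genotyping error (miscalls, allelic dropout) can flag a single offspring
  at a locus, but striking every offspring at the same locus requires $k$
  simultaneous errors, so these loci are high-confidence evidence of a
  shared paternal contribution;
* the **liberal count**: loci where *any* offspring is flagged.

Missing data create a genuine ambiguity in the conservative criterion. The
default `missing_policy = "strict"` drops a locus from the conservative set
if any offspring is uncalled there — the stricter reading, which preserves
the "conservative" character of the count. `"evaluated_only"` requires
only that every *called* offspring be flagged. Both are exposed because
upstream completeness filtering (`filter_complete_loci(g, r = 1)`) usually
makes the two coincide; when it does not, the choice should be stated with
the result.

At a maternal-homozygous locus where offspring display more than two
alleles in total, any non-maternal code counts as paternal — the criterion
is literally "differs from the maternal allele", not "equals a designated
alternate allele".

## Classifying the reproductive mode

`classify_mode()` turns the scan into calls. An offspring is **sexual**
when $\hat p_o \ge$ `sexual_min` (default 0.1) and a **parthenogen** when
$\hat p_o \le$ `parthenogen_max` (default 0.05) *and* its heterozygosity is
at most `het_ratio_max` (default 0.9) times the mother's — the automixis
signature. Everything else is **ambiguous**. The litter is called LTSS as
soon as one offspring is sexual (a single solid paternal signal falsifies
litter-wide parthenogenesis), FP when every offspring is a parthenogen,
and ambiguous otherwise. An all-male litter is reported as corroborating —
never sufficient — FP evidence.

The fraction thresholds are engineering choices derived from the error
model, and two error pathways matter:

1. A uniform miscall at rate $\varepsilon$ replaces a genotype with one of
   the three genotypes of the biallelic SNP, two of which contain the
   non-maternal allele, so a true parthenogen accrues false flags at rate
   $2\varepsilon/3$ per called locus.
2. Miscalls (and dropout) on the **mother** convert truly heterozygous
   loci into spuriously maternal-homozygous ones. At such a locus a large
   share of the offspring genuinely carry the "other" maternal allele and
   are flagged. Although these loci are few, each contributes flags to
   many offspring at once; in simulation this pathway roughly doubles the
   parthenogen null fraction relative to pathway 1 alone and fattens its
   upper tail.

At per-SNP error rates up to a few percent the combined null fraction sits
near $2 \times 2\varepsilon/3 \approx 0.013$ with excursions to ~0.03–0.04
at litter-scale locus counts (a few hundred evaluable loci). The default
`parthenogen_max = 0.05` clears that tail; `sexual_min = 0.1` clears it
with a margin while remaining far below real sexual signals, which track
the sires' non-maternal allele frequency (tens of percent — and
necessarily at least the litter's conservative fraction, since every
conservative locus flags every offspring). For substantially noisier data
the thresholds should be re-derived from the same two formulas; both are
explicit arguments of `mode_thresholds()`.

A males-only analysis (mirroring ZW expectations, where only male
offspring can be parthenogens) is available via the scan's
`offspring_ids` argument or the pipeline's `males_only` switch.

## The sibship stage

With the mother known, two offspring are full sibs exactly when they share
a sire, so a minimal multi-paternity analysis needs only pairwise full-sib
versus half-sib likelihoods. Per locus, `pairwise_sib_llr()` marginalises
the father genotype(s) over Hardy–Weinberg priors at the locus's allele
frequency: the full-sib hypothesis shares one father between the two
transmissions, the half-sib hypothesis draws two independent fathers.
Offspring genotypes are observed through a symmetric error channel that
replaces the true genotype with a uniform genotype at rate `error_rate`
(default 0.05, the scalar per-SNP error conventionally supplied to sibship
software); the mother's observed genotype is treated as true, which keeps
the per-locus likelihood identical to a small exhaustive enumeration used
as the test oracle. Loci are assumed independent and log-ratios summed.

`partition_sibships()` links pairs whose LLR reaches `llr_threshold`
(default 0; ties link) and takes connected components as paternal
full-sibships, so the component count is the minimum number of sires. This
is intentionally *not* a pedigree-reconstruction MCMC: no sibship-size
prior, no parental genotype inference, no posterior — just the grouping
and the sire bound, which is the question a single-litter study asks.

Allele frequencies default to counts over all samples including the
mother. With a single litter there is no outgroup to estimate from; the
estimate is biased toward the family's own alleles, which shrinks LLR
magnitudes but, in the recovery simulations below, does not disturb the
sign pattern the clustering uses.

## The litter simulator

`litter_sim_config()` + `simulate_litter()` generate mother-plus-litter
matrices under either hypothesis, which gives every claim above a testable
form. Choices that define the simulated conditions:

* **Allele frequencies.** Per-locus reference-allele frequencies are drawn
  uniformly from `allele_freq = c(0.05, 0.95)` by default — the spread of
  RAD SNPs after a light MAF filter. Sibship power studies use
  `c(0.3, 0.7)`, matching a high-MAF subset of a few hundred loci as used
  for sibship reconstruction in single-litter studies. Parents are drawn
  under Hardy–Weinberg equilibrium.
* **Mendelian litters** (`mode = "ltss"`): one uniformly chosen maternal
  allele plus one allele from the assigned sire, independent across loci;
  1..k sires with per-offspring assignment; offspring sex is
  Bernoulli(`sex_ratio`).
* **Automictic litters** (`fp_gametic_duplication`, `fp_terminal_fusion`,
  `fp_central_fusion`): gametic duplication yields complete homozygosity
  for one maternal allele; the two fusion variants copy the mother at her
  homozygous loci and retain heterozygosity at her heterozygous loci with
  probability `het_retention` (default 0.3). A single scalar stands in for
  the crossover-position detail a genetic map would provide — terminal
  fusion corresponds to low retention, central fusion to high — because
  the classifier only needs the qualitative homozygosity signature. All
  automictic offspring are male; infertile-ova counts are metadata only.
* **Error overlay** (`apply_genotyping_error()`): per cell, in the fixed
  order *missing → dropout → miscall* (no call ≻ partial signal ≻ wrong
  call), which keeps closed-form expectations computable. Defaults
  (dropout 0.01, miscall 0.005, missing 0) are placeholders of realistic
  magnitude for RAD data, not estimates from any particular dataset.
  Draws are keyed to cells in sorted (sample, locus) order, so the
  overlay commutes exactly with row reordering under a fixed seed.
* **Determinism.** A configuration seed reproduces output byte for byte.
  The parent, litter and error stages run on offset-derived seeds so that
  the same stream is never reused across stages (reuse would correlate,
  e.g., allele frequencies with transmission choices).

What the simulator does **not** emulate: linkage and recombination maps,
mutation, locus-specific error rates, read-level artefacts, and
population structure in the (unsampled) sires. Passing tests therefore
demonstrate correctness of the inference machinery under idealised
independent-locus conditions, not robustness to every property of real
ddRAD data.

## Numerical and degenerate-input behaviour

* Genotypes are unordered pairs, normalised to sorted order on
  construction; half-missing cells are coerced to missing with a warning.
* A fully heterozygous (or missing) mother yields an empty scan with zero
  counts and a warning, not an error; offspring with zero evaluable loci
  get `NA` fractions and are called ambiguous.
* MAF filtering counts alleles (not samples) over non-missing genotypes;
  the exact-equality mode uses a 1e-9 tolerance; loci with more than two
  observed alleles are dropped with a warning (the scan and sibship
  algebra assume biallelic SNPs).
* Sibship likelihoods skip loci where the mother or either offspring is
  uncalled or the locus is uninformative, and error out — rather than
  silently returning 0 — when nothing usable remains. `error_rate = 1` is
  rejected (the channel would carry no information; the LLR limit is 0).
* Digest coordinates are 0-based half-open (BED convention); the size
  window is inclusive on both bounds (300 ± 50 bp ⇒ [250, 350]);
  palindromic recognition sites are scanned on one strand only to avoid
  double-counting, non-palindromic sites on both with the cut offset
  mirrored; when two enzymes would cut at the same position the enzyme
  listed first labels the cut.

## Problem sizes used by the test suite

The suite validates the scan against a naive triple-loop oracle on random
matrices up to 10 × 100; Mendelian and miscall closed forms on 20,000-locus
litters of five; mode recovery on 200 replicates of 500-locus litters
across {sexual, terminal-fusion} × miscall {0, 0.01}; sibship recovery on
100 + 100 replicates of eight-offspring, 400-locus, high-MAF litters at
per-SNP error 0.05 (one and two sires); and the digest against a
brute-force string scan on 20 random sequences plus constructed edge
cases. These sizes were chosen to put Monte-Carlo standard errors well
below the effect sizes being checked while keeping the default test run
fast.

## Worked example

```{r example}
cfg <- litter_sim_config(
  n_loci = 400, n_offspring = 5, mode = "ltss",
  allele_freq = c(0.3, 0.7), seed = 11
)
sim <- simulate_litter(cfg)
g <- filter_complete_loci(sim$genotypes, r = 1)

scan <- scan_paternal_alleles(g, "mother")
scan

mode <- classify_mode(scan, offspring_heterozygosity(g), sim$meta)
mode$litter_call

sib <- partition_sibships(g, "mother", error_rate = 0.05)
glance(sib)
```

## Known limitations

* The conservative count is a screening statistic, not a calibrated test;
  its null distribution under a given error model should be simulated
  (`power_curve()`) when litters are small or error rates high.
* The classifier's heterozygosity bound is anchored to the mother's
  heterozygosity; for a nearly fully homozygous mother the automixis
  signature carries little information and calls lean on the paternal
  fraction alone.
* Sibship clustering by connected components can chain two sires'
  offspring through a single false-positive edge; with hundreds of
  informative loci the simulated risk is small, but the pairwise LLR
  table (`tidy()`) should be inspected when the partition matters.
* Which specific allele is paternal at heterozygous-mother loci is not
  identifiable without phase, and no attempt is made to reconstruct or
  identify the father.
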
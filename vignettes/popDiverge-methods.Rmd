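---
title: "Methods: inter-population divergence across multi-omics platforms"
author: "popDiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-population divergence across multi-omics platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popDiverge)
```

# Scope and model

`popDiverge` quantifies how strongly biological measurements differ
between the ancestry groups of a multi-ethnic cohort, across four kinds of
data: biallelic genotypes, multi-allelic HLA classical allelotypes,
log2-scale quantitative platforms (lipidomics, transcript expression,
miRNA, clinical variables), and their combinations in ordination. The
reference design is a three-population cohort (Chinese, Malay, Indian);
everything except the driving-pair attribution generalizes to k ≥ 2.

## Allele-frequency differentiation

For a variant with population frequencies $p_1,\dots,p_k$ the package
computes

$$F_{ST} \;=\; \frac{(k-1)\,\sigma^2}{k\,\bar p\,(1-\bar p)},$$

with $\sigma^2$ the *sample* variance of the frequencies (divisor $k-1$)
and $\bar p$ their unweighted mean. Two properties motivate this exact
form: it is invariant under allele relabeling ($p \mapsto 1-p$), and the
$(k-1)/k$ factor normalizes a fixed difference — frequencies $(0,0,1)$ —
to exactly 1. Variants monomorphic in *all* populations have an undefined
ratio and are assigned 0 with a flag. The divisor choice is not cosmetic:
with the population-variance divisor $k$ every value shrinks by a third
and the published pharmacogenomic F_ST values cannot be reproduced.

Frequencies are estimated from non-missing chromosomes only,
$p_i = \sum \text{dosage} / (2N_i^{called})$. HLA classical alleles are
handled one-vs-rest: each observed allele at a locus becomes the alternate
allele of a synthetic biallelic variant, so per-population frequencies at
a locus sum to 1 across alleles and each allele row feeds the same F_ST
formula.

**Empirical p-values.** Observed values are ranked against a genome-wide
null distribution of F_ST values using the strict-exceedance fraction
$\#\{F_{null} > F_{obs}\}/\#F_{null}$. The definition has no pseudocount,
so a value at or above the null maximum is reported as exactly 0 and
flagged; a `(count+1)/(total+1)` mode exists but is off by default because
it changes printed values. Variants below $10^{-4}$ are flagged as strong
differentiation candidates, a threshold chosen conservatively for multiple
testing and inter-variant linkage.

**Driving pair.** Reports of "driven by differences between X and Y" need
a rule; the package uses the pair with the largest two-population F_ST
(the same formula at k = 2), with ties broken by the fixed population
order and "none" when all frequencies are equal. This is an
interpretation — attribution conventions are rarely stated in print — and
it reproduces the published attributions on every testable row.

## Region scan

Each chromosome is tiled into non-overlapping windows (default 100 kb,
0-based half-open, indexed from the chromosome start so the tiling is
reproducible and independent of SNP positions). A SNP is *high* when its
F_ST exceeds the genome-wide $1-q_{high}$ quantile (default top 1%; the
published procedure names no cutoff, so it is exposed as a parameter). A
window with $n$ SNPs of which $x$ are high is scored with the exact
binomial tail $P(X \ge x)$, $X \sim \mathrm{Bin}(n, q)$, where $q$ is the
realized genome-wide high fraction (equal to $q_{high}$ up to ties). The
tail is an explicit summation of `dbinom` terms; tests require agreement
with the survival function to $10^{-10}$ up to $n = 1000$. Significance is
Bonferroni over occupied windows at $\alpha = 0.05$, and maximal runs of
adjacent significant windows merge into regions (exported as BED). Empty
windows are excluded rather than scored.

## Group contrasts

Per feature, the null hypothesis of identical group means is tested with
the partial F-test comparing `y ~ population + covariates` against
`y ~ covariates`; with no interaction terms this equals the Type-III test
for the population factor, which remains correct under imbalance. Samples
missing the feature value are dropped featurewise; samples missing a
covariate are dropped platform-wide; a population reduced below two
observations skips the feature with a flag, and covariates aliased with
the model raise an error naming the covariate rather than silently
dropping terms.

Least-squares means are computed from the fitted model by averaging
predictions over the balanced grid of all factor-level combinations
(continuous covariates, if any, held at their mean). In balanced designs
this reduces to raw group means and balanced batch effects cancel in lsm
*differences*; in confounded designs it matches `emmeans`, which the test
suite uses as an independent cross-check. Fold changes on log2 platforms
are $2^{lsm_a - lsm_b}$, so reciprocity $FC(a,b)\,FC(b,a) = 1$ is exact.
The within-platform Bonferroni factor is the number of features *actually
tested* (skipped features do not count), and the per-feature driving pair
is the pair with the largest absolute lsm difference.

## Lipid tagging

Within one population, squared Pearson correlations are computed between
all feature pairs on pairwise-complete observations (minimum 3 shared
samples; zero-variance features get undefined correlations and are forced
to singletons). Tag selection is a greedy maximum-degree cover of the
graph whose edges are $r^2 > 0.8$: repeatedly pick the feature with the
most uncovered above-threshold neighbors (ties: larger mean $r^2$ to those
neighbors, then lexicographic ID), make it a tag, and mark its uncovered
neighbors as tagged by it. Tagging is *direct* — every tagged feature must
itself exceed the threshold with its tag, mirroring tag-SNP semantics — and
a transitive-closure mode (connected components) is available for
comparison since published counts cannot distinguish the two without the
underlying data. The bookkeeping identity is
`n_representative = K − n_tagged` where `n_tagged` counts cluster members
other than their tags; applied to a 282-species panel with clusters of
71/29, 61/26 and 60/26 members/tags it yields 240, 247 and 248
representatives.

## Ordination

PCA is an SVD of the standardized sample×feature matrix. Genotype mode
centers each SNP by $2\hat p$ and scales by $\sqrt{\hat p(1-\hat p)}$ (the
smartPCA convention, which equalizes drift variance across allele
frequencies); quantitative mode z-scores columns — chosen over
centering-only because clinical and dietary variables mix units, and
flagged as a choice since either convention is defensible for
single-platform matrices. Missing entries are column-mean imputed for the
decomposition only and never written back; constant columns are dropped
with a flag. Component signs are fixed (largest-magnitude loading
positive) so outputs are reproducible; eigen-sign is otherwise arbitrary.
LD thinning before genotype PCA is a greedy positional pass dropping any
SNP with genotype $r^2$ above a cutoff to a retained SNP within a window,
followed by seeded down-sampling to a target count.

## Quality control

The genotype cascade mirrors standard array QC, applied in order and
recorded stage-by-stage in a `QcReport` whose validity enforces
removed + retained = input: array merge (overlapping SNPs keep the copy
with less missingness, ties keep the first input), list-based exclusion of
duplicates/related/ethnicity-discordant samples (no genetic inference is
performed — those call for dedicated tooling and the source procedure is
unspecified), sample missingness > 2%, SNP missingness > 5% (both strict
inequalities, so a sample or SNP exactly at the threshold survives), and
the Hardy-Weinberg exact test within each population at $p < 10^{-3}$.

The HWE test is the exact conditional test: two-sided, summing the
probabilities of heterozygote counts no more likely than the observed one
under the distribution conditional on allele counts, computed with the
numerically stable mid-out recurrence. The exact test was chosen over the
chi-square because exome-array content implies many low minor-allele
counts where the asymptotic test misbehaves; whether the source pipeline
tested founders only or all samples, or used a one-sided variant, is not
recorded, so exact two-sided on all samples is the documented default. A
variant failing in *any* one population is removed (configurable to
fail-all). Call-rate rules keep both published boundary conventions:
miRNAs are removed at call rate ≤ 90% (a feature exactly at 90% goes),
clinical variables at missingness > 20% (a variable exactly at 20%
stays), and the concordance filter for replicated panels removes SNPs
agreeing in < 95% of shared non-missing genotype pairs.

# The synthetic cohort generator

The generator exists so that every downstream stage has a substrate with
*known* truth; its defaults are the study conditions, chosen once:

* **Samples** 122/120/122 across Chinese/Malay/Indian, sex balanced
  binary, batch/RT-plate a 3-level round-robin — the minimal confounders
  that exercise covariate adjustment.
* **Genotypes**: ancestral frequencies Uniform(0.05, 0.95), population
  frequencies Balding–Nichols $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$
  with F = 0.01 by default, matching genome-wide pairwise differentiation
  of one to a few percent between these groups; genotypes binomial under
  HWE; positions at a fixed 10-kb stride (1000 SNPs per synthetic
  chromosome) so every 100-kb window deterministically holds 10 SNPs.
  Balding–Nichols was chosen because its single parameter *is* the
  expected F_ST, making parameter recovery a direct test: mean per-SNP
  F_ST must be monotone in F, and lands in [0.005, 0.02] at F = 0.01.
  F = 0 and F = 1 are rejected (degenerate Beta).
* **HLA-like loci**: per-population allele-frequency simplexes drawn
  Dirichlet(1,…,1), two alleles per sample drawn independently within
  population.
* **Quantitative platforms**: per-feature baselines Uniform(2, 15) on the
  log2 scale with unit noise; lipid blocks share a latent factor with
  loading $\sqrt r$, $r = \sqrt{\texttt{block\_r2}}$, so within-block
  pairwise $r^2 \approx$ `block_r2` (default 0.8, the tagging threshold);
  additive sex and batch effects drawn N(0, 0.2) per feature — modest by
  design so they perturb the contrasts without washing out the block
  correlations; planted group shifts of `effect_size` (default 1.5)
  within-group SDs on the first `n_diff_features` features, rotating over
  populations, recorded exactly in the `truth` slot.
* **Missingness** uniform at 1% per entry, enough to exercise every QC
  path at the default thresholds.

A fixed seed reproduces the cohort byte-for-byte. The generator
deliberately omits linkage-disequilibrium haplotype structure (loci are
independent), heavy-tailed lipid distributions, platform-specific
normalization artifacts, and any dietary-questionnaire structure. Passing
tests therefore demonstrate statistical correctness of the methods under
their stated models — calibrated type-I error, full power at planted
effect sizes, exact recovery of planted windows and blocks — not
robustness to everything real cohort data can do.

# Numerical choices and problem sizes

Tolerances in the test suite reflect how each quantity is computed: exact
combinatorial quantities (HWE p-values vs a log-factorial enumeration
oracle, binomial tails vs the survival function, correlation vs the
covariance formula) agree to $10^{-10}$–$10^{-12}$; linear-model
quantities (partial F vs a sums-of-squares oracle, lsm vs a
prediction-grid oracle and `emmeans`) to $10^{-8}$–$10^{-10}$; calibration
bands follow binomial sampling error at the stated replicate counts
(e.g. type-I error in [0.03, 0.07] over 1000 null features).

Simulation sizes were set to make each recovery statement sharp yet quick:
2,000-SNP backgrounds with one planted 10-SNP window over 20 seeds for the
region scan, 200-feature platforms with 10 planted shifts at 100
samples/group over 50 seeds for the contrasts, 3,000 loci for
divergence-parameter recovery. At these sizes the planted-signal tests
have essentially no stochastic margin (power ≈ 1, family-wise false-positive
rate ≤ α), so the ≥ 90%-of-seeds acceptance thresholds are comfortably
conservative.

Degenerate inputs are decided, not left to chance: monomorphic variants
score F_ST 0 with a flag; a population with no called genotype at a
variant excludes that variant from F_ST; empty windows are excluded from
the scan; zero-variance features become singletons in tagging and are
dropped in PCA; an empty null distribution, an empty platform, or fewer
than two occupied windows raise errors.

# Known limitations

* Only the variance-ratio F_ST form above is provided; estimator families
  with different weighting (Weir–Cockerham, Hudson) are out of scope.
* The driving-pair rule and the greedy tagging cover are documented
  interpretations of results whose generating procedures are not public;
  alternative covers (e.g. minimal set cover) can differ on dense graphs.
* Duplicate/relatedness detection and genotype-based ancestry assignment
  are list-based hooks, not inference.
* The published cohort-scale inventories (counts of differentiated
  regions, probesets, lipids, clinical variables) depend on
  controlled-access data and are not reproduced; the synthetic recovery
  suite stands in for them.
* PCA does not replicate smartPCA's iterative outlier removal, which the
  source analysis did not report using.
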
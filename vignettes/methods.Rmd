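---
title: "Methods: deriving and stress-testing a vascular-invasion expression predictor"
author: "visig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and stress-testing a vascular-invasion expression predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `visig`, the
assumptions behind it, the tunable parameters that matter, and the design
choices we made where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The scientific setting

Vascular invasion (VI) — tumor cells inside the lumen of a vein or muscular
artery — is a high-risk feature of stage I lung adenocarcinoma that is
diagnosed on resected tissue. A three-level grading scale orders tumors as
LMP (low malignant potential) < NST (no special type) < VI. The package
derives a VI-associated gene-expression signature from bulk RNA-seq of
graded tumors, compresses it into a 48-gene ridge-logit predictor, and
quantifies the properties that decide whether such a predictor can work on
small pre-surgical biopsies: stability across tumor regions, spatial reach
beyond the invaded focus, and prevalence-adjusted predictive values.

## 2. Normalization and filtering

Counts live in a `ViCountSet` (a `SummarizedExperiment` with mandatory
`lib_size` and `norm_factor` columns). Normalization is classic TMM
(trimmed mean of M-values, 30% trim on M, 5% on A, inverse binomial
variance weights, reference chosen by the 75th-percentile rule), delegated
to edgeR's canonical implementation and cross-checked in the tests against
a direct evaluation of the published formula. Genes are kept when CPM > 1
in at least `ceiling(0.10 * n)` samples, computed on raw library sizes —
the convention of the edgeR workflow. `logCPM` uses a prior count of 0.5
(the toolkit's habit; the value is not critical and is exposed); the
normalization factors are rescaled to geometric mean 1 inside `logCPM`, so
per-gene z-scores are invariant to a global rescaling of the factors.

## 3. Differential expression

`nbGlmLrt` fits a gene-wise negative binomial log-link GLM with offsets
`log(lib_size * norm_factor)` and tests contrasts by likelihood ratio
(chi-squared, df = number of dropped coefficients). The canonical design is
`~ grade` with LMP as baseline and the `gradeVI` coefficient tested;
additional covariates (e.g. lymphatic invasion) are handled by augmenting
the design and testing the corresponding contrast. Dispersion estimation
uses edgeR's empirical-Bayes machinery (common/trended/tagwise); with a
fixed `dispersion` argument the estimation step is bypassed, which the
tests use to verify the Poisson limit (relative deviance difference < 1% at
phi = 1e-6) and calibration under the generator's null (p-values uniform
within Kolmogorov distance 0.05 at 2000 genes).

## 4. Clustering the signature and choosing k

Significant genes (BH FDR < 0.01) are clustered on their z-scored logCPM
profiles with Ward.D2 on Euclidean distances. The number of clusters comes
from Monti-style consensus clustering: repeated 80% gene subsamples, Ward2
labels per candidate k, pairwise co-clustering frequencies normalized by
co-sampling counts, and the area under the empirical CDF of off-diagonal
consensus values per k. We compute the area as `1 - weighted mean` of the
consensus values (left-endpoint rule over the sorted unique values), so the
delta-area between consecutive k equals the expected drop in co-clustering
probability — an interpretable scale.

**Elbow threshold.** The chosen k is the largest whose delta-area is at
least `elbowFrac` of the k = 2 area. The delta gained by isolating a true
cluster scales with its share of gene pairs: a cluster holding ~8% of the
signature (like the smallest of the four planted clusters, 37/474 genes)
contributes roughly 9% of the k = 2 gain. The default `elbowFrac = 0.05`
keeps such clusters above threshold while unstable noise splits — which
produce intermediate consensus values rather than crisp separation — fall
below it.

**A caveat we verified.** Consensus clustering on a *fixed* data matrix can
report apparently stable sub-splits of a homogeneous cluster (the familiar
null-stability criticism of the method): Ward half-splits of a generic
Gaussian blob survive 80% subsampling. On the synthetic cohort this does
not bite — splits beyond k = 4 peel small unstable groups — but users
should read the delta-area sequence, not just the chosen k. Gene
subsampling is the default; sample subsampling is available via
`sampleFraction`.

## 5. The 48-gene predictor

Feature selection is cluster-proportional: quotas by largest-remainder
apportionment of 48 over the clusters' shares of significant genes
(e.g. sizes 115/37/182/140 of 474 give quotas 12/4/18/14), filled within
cluster by ascending p-value (ties: larger |log2FC|, then gene ID — the
within-cluster rule is our assumption; only the proportionality is
prescribed). The ridge binomial logit minimizes
`-(1/n) loglik + (lambda/2)||beta||^2` with an unpenalized intercept by
damped Newton iterations to gradient norm < 1e-8; per-observation scaling
makes the fit invariant to duplicating the data, and the tests check the
optimum against an independent BFGS optimizer to 1e-6. The penalty grid is
25 log-spaced values in [1e-3, 1e3] on the standardized scale (the original
grid is unpublished); inner-CV AUROC ties resolve toward the larger
penalty. Outer 70/30 splits are stratified by VI label — stratification is
our choice, to guarantee class presence in every split. Selection contrasts
VI vs LMP while evaluation is binary VI vs rest, mirroring how the
predictor would be used. When an outer-train fold has fewer than 48
FDR-significant genes (routine under label permutation), selection falls
back to the top 48 by p-value with a warning, keeping the panel size fixed.

The Youden cutoff maximizes sensitivity + specificity - 1 over midpoints of
adjacent distinct scores; ties take the lowest cutoff (favoring
sensitivity, the clinically safer direction here). Positivity is strict
(`score > cutoff`); the boundary rule is a documented convention.

Cross-cohort transfer uses per-gene moment matching to the discovery
cohort (`x' = (x - m_t)/s_t * s_r + m_r`). Note a structural fact the tests
assert: a cohort-wide per-gene shift moves every sample's linear score by
the same constant, so within-cohort ranks and AUROC are unaffected by both
the shift and the adjustment — what the adjustment restores is the
*calibration* of the transported Youden cutoff (sensitivity + specificity
at the fixed threshold).

## 6. Scoring

Three score types: (i) mean z-score of a cluster's genes per sample;
(ii) control-bin module scores for spots (24 equal-frequency bins of
average expression, ties to the lower bin; 100 control genes per set gene
sampled with replacement within bin; score = set mean minus pooled control
mean — the cited scoring function's defaults, since the original settings
are unstated); (iii) the predictor spot score, module(up) - module(down),
computed with a shared seed so swapping the sets negates the score exactly.
Spot counts are log-normalized (`log1p` of depth-normalized counts scaled
to 1e4); the variance-stabilizing transform used for merged spatial samples
upstream is out of scope and this simpler transform substitutes within the
module's contract.

## 7. Spatial analysis

Spots with fewer than 250 detected genes are dropped. The spatially
weighted correlation ranks both scores globally (Spearman mode), then
computes a kernel-weighted local Pearson correlation per spot over
neighbors within the bandwidth, and averages local coefficients per sample.
The bandwidth is interpreted as 5 lattice units (multiples of the spot
spacing) with a bisquare kernel; because the original unit convention
("bandwidth = five") is ambiguous, kernel, method and spacing are all
exposed, and the uniform-kernel infinite-bandwidth limit provably equals
the global Spearman correlation (tested to 1e-6). Distance binning around
annotated invasion foci is Euclidean on spot centers with a 1 mm threshold;
exactly 1 mm is proximal (the printed "<1 mm from and including" versus
">1 mm" leaves the boundary unassigned; we chose inclusive-proximal).
Samples with no focus in the capture area are entirely distal.

## 8. Heterogeneity analysis

Every multi-region tumor is down-sampled to one random region pair
(intra), matched by an equal number of inter-tumor pairs (two distinct
tumors per draw, drawn with replacement across draws). Absolute score
differences are compared by two-sided rank-sum test; matched-region
agreement is Spearman's rho, which under the generator's model attenuates
as `sigma^2 / (sigma^2 + tau^2)` (tumor signal variance over total) — the
tests check this closed form at n = 500. Gene-level reproducibility ranks
(per-gene Spearman across region pairs; Spearman chosen for consistency
with the pair-level analysis, the original statistic being unstated) feed a
pre-ranked GSEA: weighted-KS running sum with hit increments proportional
to |value|^1, set-permutation null, NES = ES over mean |null ES| of the
same sign, and a two-sided permutation p (fraction of |null| >= |ES|, +1
smoothing) — a definition that is exactly uniform-calibrated under random
sets, which the tests verify.

## 9. Diagnostic accuracy

Confusion counts at the prespecified cutoff give Clopper–Pearson exact
intervals (Beta quantiles; closed at 0/1 boundaries) and Beta posteriors
under uniform priors: `se ~ Beta(1+TP, 1+FN)`, `sp ~ Beta(1+TN, 1+FP)`.
`projectPpvNpv` draws 10,000 paired posterior samples once and reuses them
across the prevalence grid (15–35%), so PPV is nondecreasing and NPV
nonincreasing in prevalence draw by draw; summaries are the median and
2.5th/97.5th type-7 (linear-interpolation) percentiles — the quantile
definition is our choice, as is the strict cutoff. The integer counts
(10, 2, 11, 1) used in the acceptance script are the unique ones consistent
with sensitivity 0.83 and specificity 0.92 on 12 + 12 specimens.

## 10. What the synthetic generator emulates — and what it does not

`generateBulkCohort` draws NB counts (`Var = mu + phi mu^2`, one shared
phi = 0.15 by default; per-gene dispersion is a straightforward extension)
with grade effects coded LMP = 0, NST = `nstEffectScale`, VI = 1 as
multipliers on each cluster's log2 fold change, producing the
LMP < NST < VI gradient. The NST attenuation of 0.5 is a modeling choice —
the relative magnitude is not reported. Four mutually exclusive gene
clusters of sizes 115/37/182/140 (defaults; three up, one down, log2FC
1.5/2.0/1.2/-1.5) are planted on baselines drawn log-normal on the log2-CPM
scale and rescaled to sum to 1e6, with ~5% of genes planted below the CPM
filter. Each cluster also carries a latent per-sample factor
(`clusterCorSd = 0.8`, log2 scale): without it, three same-direction
clusters would be indistinguishable co-expression-wise and no clustering
method could recover k = 4; its default makes the planted blocks about as
crisp as the heatmap-visible structure the signature derivation relies on.
Library sizes are log-normal (median 2e6); a `batchShiftSd > 0` applies one
per-gene N(0, sd^2) log2 offset to the whole cohort, the scenario the
reference adjustment addresses.

The generator does **not** emulate: read-level data, isoform structure,
gene–gene correlation beyond the planted clusters, count-level spatial
data beyond Poisson pseudo-bulk mode, or cohort-specific technical
artifacts (degradation, GC bias). Passing recovery tests therefore shows
the pipeline is correct and well-calibrated under its own model; it does
not certify performance on real cohorts, where dispersion is gene-specific,
clusters are fuzzy, and batch effects are not purely additive.

## 11. Numerical conventions and degenerate inputs

* Zero p-values are floored at the smallest positive double before
  `-log10(p)`; ranking ties break by |log2FC|, then gene ID.
* Constant genes z-score to zero (with a warning); constant panel genes at
  training time are an error.
* Separation at lambda = 0 is an error (any positive penalty restores a
  well-defined optimum); the Newton step falls back to a ridge-damped
  solve if the Hessian is singular.
* All-zero samples are rejected before TMM; empty filter results warn.
* Every stochastic routine takes an explicit seed and is bitwise
  reproducible; generators return truth tables for recovery testing.

## 12. Problem sizes used by the shipped tests

The test suite exercises the full pipeline at sizes chosen to keep the
default run comfortably interactive while preserving the cohort structure:
the standard synthetic cohort is 100 samples x 2000 genes with the full
474-gene planted signature; nested CV runs 15 outer splits in the
end-to-end test (the function default remains 100); consensus selection
uses 40 subsamples there (default 100); the heterogeneity suite uses 63
tumors x 2 regions over 20 seeds, and the attenuation check 500 tumors.

## 13. Known limitations

* The consensus-clustering k rule inherits the method's null-stability
  caveat (Section 4); inspect the delta-area sequence.
* The module score measures spot-specific enrichment relative to
  expression-matched controls; cohort-level mean shifts partially
  self-normalize, so cross-sample comparisons should use a common bin
  structure or the mean z-score instead.
* `referenceAdjust` matches first and second moments per gene only; it
  cannot remove batch structure *within* a target cohort.
* The model family is the ridge binomial logit throughout; the original
  multi-model selection harness is not reproduced (its winning model and
  hyperparameter scheme are what the package implements).
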
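---
title: "Fibroblast senescence signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibroblast senescence signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

Cancer-associated fibroblasts (CAFs) that undergo cellular senescence
remodel the tumor microenvironment: they interact more intensely with
immune cells, are associated with reduced cytotoxic infiltration, and
carry a transcriptional program that is informative about both prognosis
and response to immune checkpoint inhibition (ICI). `fibrosen`
implements the complete computational chain for exploiting that program:

1. per-cell senescence scoring of single-cell tumor transcriptomes;
2. construction of a fibroblast senescence-associated signature (FSS)
   across many single-cell datasets;
3. scoring of bulk cohorts with the signature, immune-abundance proxies,
   and stratification by FSS score and tumor mutation burden (TMB);
4. an ICI-response classifier harness over signature-gene features;
5. a multi-task logistic regression (MTLR) survival model with
   differential-expression feature selection;
6. integration of CRISPR-screen fitness data to nominate hub genes at
   the intersection of all evidence streams.

Every stage is exercised end-to-end on synthetic data with planted
ground truth, so each claim the pipeline makes (signature recovery,
subgroup ordering, survival concordance, hub nomination) is validated
against a known generating process.

## Per-sample enrichment scoring

Senescence scores are single-sample gene-set enrichment statistics
computed from scratch. For an expression matrix with `p` genes and `n`
samples, each gene is first rank-transformed across samples. In `ecdf`
mode the statistic is the empirical CDF of the gene evaluated at each
sample, `z_ij = (1/n) #\{k : x_ik <= x_ij\}`; this is deterministic,
fast, and invariant to monotone transforms, which suits sparse
log-normalized single-cell data. In `gauss` mode the empirical CDF is
smoothed with a Gaussian kernel of bandwidth `sd_i / 4`, which suits
continuous bulk profiles; a zero-variance gene falls back to a
vanishingly small bandwidth so that ties resolve to central values
instead of NaN.

Per sample, genes are ordered by decreasing `z` (ties broken by
ascending gene index for reproducibility) and a weighted
Kolmogorov–Smirnov walk is taken down the list: an in-set gene at sorted
position `s` (rank `rho = p - s + 1`, so the top of the list carries
rank `p`) contributes its symmetric rank weight `|p/2 - rho|^tau`
normalized by the total in-set weight, while an out-of-set gene
subtracts `1/(p - |set|)`. The enrichment score is the maximum positive
excursion plus the minimum negative excursion of the walk, so it lies in
`[-1, 1]`. When a singleton set sits exactly at the zero-weight rank the
in-set steps fall back to uniform weights so the walk still deposits
unit mass. Both kernels are implemented in C++ (the walk involves a sort
per sample; the Gaussian CDF is quadratic in sample count) and are
verified against a step-by-step brute-force R implementation on hundreds
of random instances to 1e-12.

Scores are min–max normalized within each dataset (`(x - min)/(max -
min)`; a constant vector maps to 0.5 with a warning), and cells are
split into high-senescent (HS) and low-senescent (LS) groups at the
population median, with ties deterministically assigned to LS. Whether
normalization should be per dataset or pooled across datasets is not
determined by the underlying method; the package normalizes per dataset,
which makes scores comparable within the unit each median split acts on.

## Signature construction

Within each single-cell dataset the package computes, for fibroblasts
passing QC:

* **FS_x** — genes positively Spearman-correlated with the per-cell
  senescence score (tie-corrected ranks, two-sided t-approximation,
  Benjamini–Hochberg FDR < 0.05, R > 0). Only genes detected in at
  least 10% of fibroblasts are tested: Spearman correlation on an
  all-zero gene is undefined, and the threshold mirrors the marker
  `min.pct` convention.
* **FS_y** — genes upregulated in the fibroblast cluster (two-sided
  Wilcoxon rank-sum on log-normalized expression with normal
  approximation and tie correction; log2 fold change of
  backtransformed means with pseudocount 1; retained when
  `log2FC > 0.25` and detection `>= 0.1` in the more-detected group).
  Only positive fold changes are kept — the signature seeks
  fibroblast-*up*regulated senescence genes — and no additional
  adjusted-p cutoff is applied at this stage; the BH-adjusted p-value
  is carried along for downstream use.
* **FS_n = FS_x intersect FS_y**, carrying the FS_x correlation.

Per-gene evidence is aggregated across datasets by the geometric mean of
the Spearman R over the datasets whose FS_n contains the gene; members
are genes with geometric mean above 0.25 supported by at least 25% of
datasets. Restricting the geometric mean to supporting datasets is a
deliberate reading of an ambiguous aggregation rule: including absent
datasets as zeros would annihilate every gene, and the added
minimum-support fraction guards against single-dataset flukes. BH
correction is applied within each dataset independently, matching the
per-dataset construction.

## Bulk scoring and stratification

Bulk cohorts are scored with the signature using the `gauss` kernel.
Immune-population abundances are marker-mean scores — the arithmetic
mean of a marker set's log-expression — rather than a curated
deconvolution panel: the curation is data, not method, and any GMT can
be supplied. Samples are stratified at pooled medians into high/low FSS
(HF/LF) and high/low TMB (HT/LT), with ties going to the low label, and
the four combined groups HFHT/HFLT/LFHT/LFLT partition the samples.
Pairwise group comparisons use two-sided Mann–Whitney tests with BH
correction. On synthetic data the cytotoxic marker score reproduces the
expected immune-potency ordering LFHT > LFLT > HFHT > HFLT.

## ICI-response harness

Cross-cohort batch structure is removed by per-cohort gene-wise
standardization — a declared, rank-preserving surrogate for
empirical-Bayes batch correction, whose bespoke machinery contributes
nothing to the method itself. Cohorts are split 8:2 with a
round-half-up training size and largest-remainder class stratification
(821 samples yield exactly 657/164). The classifier is a
gradient-boosted tree ensemble grid-searched by mean AUC over stratified
10-fold cross-validation repeated 5 times (the CV scheme is pinned to
this reading and is configurable), with a logistic baseline; other
learners can be plugged in through the same interface but are out of
scope. AUC uses the Mann–Whitney formulation with ties counted 1/2.
Predicted-risk groups are compared by Kaplan–Meier curves and the
two-group log-rank test via the survival package. The harness itself is
single-seeded and fully deterministic given that seed; repeating the fit
across seeds and keeping the best validation AUC is a one-line outer
loop left to the caller, since baking best-of-`k` selection into the
harness would silently optimize on the validation set.

## MTLR survival model

The prognostic model discretizes time at `m = ceil(sqrt(#events))`
boundaries (clamped to [2, 30]) placed at interior quantiles of the
event times — the discretization convention of the reference MTLR
implementation. Each subject corresponds to a monotone binary sequence
over the grid; the score of the sequence that dies in interval `j+1` is
the sum of the per-interval logistic scores beyond `j`. Uncensored
subjects contribute their sequence's softmax probability; a subject
censored in interval `i` contributes the summed probability of every
sequence with death interval `>= i` — the death may still occur later in
the censoring interval, the standard conservative convention. The
objective adds a ridge penalty `C1/2 sum ||theta_k||^2` and a temporal
smoothness penalty `C2/2 sum ||theta_{k+1} - theta_k||^2` (on by
default; it stabilizes small-n grids) and is minimized by BFGS from zero
initialization, so fitting is deterministic; with a single interval and
no censoring the model provably reduces to ridge-penalized logistic
regression, which the tests verify against an independent optimizer.

The risk score is `sum_k (1 - S(t_k))`, the expected number of grid
intervals died through: it is monotone in predicted death mass and gives
a grid-independent ordering for proportional hazards. Feature selection
(MTLR_DE) takes the `n` smallest-p genes from a two-sided Wilcoxon test
between poor outcomes (death before the median observed time) and good
outcomes (survival to at least the median); patients censored before the
median are excluded because their class is unknown — the reference
procedure leaves this case unspecified, and exclusion is the choice
least likely to contaminate either class. Concordance is Harrell's C
over pairs `(i, j)` with `t_i < t_j` and an event at `t_i` (ties 1/2);
Uno's censoring-weighted variant with `G(t-)^-2` IPCW weights and a
90th-percentile horizon is available.

## CRISPR integration

Per-screen logFC values are z-scored with the sample (n-1) standard
deviation — the convention must be pinned for reproducibility — which
removes dataset-specific location and scale. Genes are aggregated by the
mean z over the screens measuring them (minimum support 1, because real
screen collections have heterogeneous coverage) and ranked ascending:
the most negative aggregated z, i.e. the strongest depletion under
immune pressure, is rank 1. The source descriptions of ranking direction
conflict; the package pins the reading in which knocking out a top-ranked
gene enhances antitumor immunity, and exposes a flag to flip it. The top
10% are flagged, signature enrichment among flags is an upper-tail
hypergeometric test (identical to one-sided Fisher), and hub genes are
the intersection of flagged signature genes with the survival model's
features.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with known truth planted at every level:

* **Single cell.** Six cell types with configurable proportions; a
  latent senescence state `s` per cell in [0, 1] — Beta(5, 2) in
  fibroblasts, Beta(2, 5) elsewhere, matching the min–max-normalized
  score range used downstream. Counts are negative binomial with a
  single global dispersion (size 30) around `depth * exp(log-mean)`,
  with baseline log-means Normal(1, 1) per dataset and log-normal depth
  (median library ~10k counts over a 1000-gene universe). The
  senescence set gains `gamma*s` in every cell; 40 planted
  fibroblast-senescence genes gain `beta*s` plus the marker shift in
  fibroblasts only; each type has 25 disjoint markers shifted by
  `marker_effect = 2` (~7-fold enrichment, typical of canonical
  cell-type markers). Mitochondrial genes carry the `MT-` prefix so QC
  code is realistic, and 10% of cells have depth scaled by 0.05 to
  exercise the QC filter. At these settings the planted genes' mean
  within-fibroblast Spearman correlation with `s` is ~0.35 and the
  per-cell score tracks `s` at rho ~0.9, so recovery tests probe a
  realistic but not trivial regime. The operating point matters: with
  substantially noisier counts the pinned `beta = 1` slope is not
  recoverable by any method, and with pan-cell senescence genes more
  fibroblast-enriched they would contaminate the signature.
* **Bulk.** Each sample carries a latent burden `S ~ Beta(2, 2)` and
  fibroblast fraction `f ~ Beta(6, 18)`; planted genes gain
  `beta*S*f/0.25` (the burden signal rides on the fibroblast
  compartment), cytotoxic markers decrease in `S` and increase in
  log-TMB, cohorts get additive Normal(0, 0.5^2) per-gene batch
  offsets, and residual noise is Normal(0, 0.3). Survival is
  exponential with rate `h0 exp(1.5 S)`; the independent exponential
  censoring rate is calibrated by bisection to a 30% censored fraction
  (no censoring model is prescribed by the underlying study). Response
  is Bernoulli(`sigmoid(1 - 3 S)`) and TMB is log-normal, independent
  of `S`. With a continuous burden and this response model the best
  achievable response AUC — even from the true `S` — is about 0.7, so
  classifier checks are calibrated against that ceiling rather than an
  arbitrary target.
* **Screens.** Dataset `d` measures 90% of the universe with
  `logFC ~ Normal(mu_d, sigma_d^2)`, `mu_d ~ Normal(0, 0.5^2)`,
  `sigma_d ~ Uniform(0.5, 2)`; 25 planted resistant genes are shifted
  by `-delta = -2`, 15 of them drawn from the planted
  fibroblast-senescence genes so that a triple-evidence hub exists.

What the generator does **not** emulate: ambient RNA, doublets, UMI
saturation, cancer-type-specific biology, non-proportional hazards, and
gene–gene correlation beyond the shared latent factors. Passing tests
therefore demonstrate that the pipeline recovers planted structure of
the assumed form at realistic noise levels — not that it is robust to
every artifact of real tumor data.

## Reference problem sizes

The reference simulation used throughout the tests is 8 single-cell
datasets of 1500 cells over 1000 genes, a 400-sample 4-cohort bulk
collection, and 17 screens — large enough that every recovery statistic
is well-resolved while a full pipeline run stays under a minute. The
hub-recovery property is evaluated over 20 independently seeded runs of
the hub-relevant stages (the response classifier does not feed the hub
list and is skipped there). The survival-model recovery check uses an
independent exponential-hazard simulation at n = 500.

## Known limitations

* The enrichment statistic implements a single (default) combination
  rule — maximum positive plus minimum negative excursion; the
  max-absolute-deviation alternative is exposed but not default.
* Immune scores are marker means, not deconvolution estimates; absolute
  abundances across populations are not comparable.
* The batch surrogate equalizes first and second moments per cohort
  gene-wise; higher-order cohort effects survive it.
* The MTLR grid is shared across subjects; time-varying covariates are
  out of scope.
* Only the gradient-boosted and logistic classifiers ship; the harness
  accepts alternatives but none are bundled.
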
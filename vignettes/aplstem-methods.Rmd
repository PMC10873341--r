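---
title: "Methods: deconvolution, stemness scoring and synthetic validation in aplstem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolution, stemness scoring and synthetic validation in aplstem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aplstem)
```

`aplstem` estimates the abundance of leukemic stem-like cells in acute
promyelocytic leukemia (APL) bulk transcriptomes, scores leukemic
stemness with an 11-gene panel, and stratifies survival by that score.
This vignette is the package's account of the underlying models, the
parameters that matter, the synthetic data used to validate every
stage, and the design decisions that were genuinely open.

## The cellular model

APL blasts are treated as a mixture of six transcriptional branches —
stem-like, Prog-like, GMP-like, cycling GMP-like, S100hiGMP-like and
MDP-like — alongside three non-leukemic populations (T/NK, B,
erythroid). `apl_populations()` returns these nine names and every
stage is written against them. The stem-like branch is rare (a few
percent of blasts) but sits at the root of the differentiation
hierarchy, which is why its estimated proportion, rather than overall
blast burden, is the quantity of interest.

## Single-cell preprocessing

`qc_filter()` removes cells expressing fewer than 300 genes, with total
counts below 500 or above 30,000, or with more than 10% mitochondrial
counts. All four rules are strict exclusions, so a cell sitting exactly
on a boundary (300 genes, 500 or 30,000 counts, 10.0% mito) is
retained; the tests pin this down on a hand-enumerated six-cell matrix
(`qc_demo_matrix()`). Mitochondrial genes are recognized by the `MT-`
name prefix; when none exist the rule is skipped with a warning rather
than silently passing everything. Doublet removal is out of scope; the
QC report carries a placeholder column so its schema is stable.

Normalization is counts-per-scale (`normalize_cpm()`, default CPM,
optionally log2(x+1)). No gene-length correction is applied: UMI counts
have no length bias, and bulk inputs enter the pipeline already as TPM
and are never re-derived.

`select_hvg()` ranks genes by the mean/variance-plot convention:
dispersion is the variance-to-mean ratio of linear CPM, log-transformed
and z-scored within 20 equal-frequency mean bins, so genes are compared
against peers of similar expression rather than rewarded for scale.
Constant genes get dispersion 0 and always rank last; remaining ties
break by raw dispersion and then gene order, making the ranking fully
deterministic.

`find_markers()` performs per-gene two-group Wilcoxon rank-sum tests on
linear CPM, using the normal approximation with tie and continuity
correction — the documented default of the single-cell toolchain this
replaces, and verified in the tests against `stats::wilcox.test`
gene by gene. Fold change is log2((m₁+ε)/(m₂+ε)) with ε = 1e−9 to avoid
division by zero. Genes are excluded before testing when detected in no
more than `min_pct` of cells in both groups or when |log2FC| falls
below the reporting floor (0.01); Benjamini–Hochberg correction is
applied across the genes actually tested. Significance defaults are
log2FC > 0.58 (fold change 1.5), detection > 0.1, adjusted *P* < 0.05;
cross-population comparisons conventionally relax the fold-change bar
to 0.26 (fold change 1.2), and both are plain arguments. Which of the
two thresholds feeds the stemness candidate pool is exposed as
configuration rather than fixed, since either is defensible.

## KNN label transfer

`build_joint_embedding()` places reference and query cells in one PCA
space anchored entirely on the reference: HVGs are chosen on the
reference, both matrices are log-CPM normalized, each gene is centered
and scaled by the *reference* mean and standard deviation, principal
directions come from the reference alone, and query cells are
projected. A query cell with counts identical to a reference cell
therefore receives identical coordinates — the property that makes
nearest-neighbor transfer meaningful. Published batch-correction
methods are deliberately not re-implemented; on data with real batch
structure the embedding should be built on harmonized matrices
upstream. The synthetic validation data contain no batch effects, so
passing tests demonstrate the transfer contract, not robustness to
batch confounding.

`knn_transfer()` takes the k = 50 Euclidean nearest *reference*
neighbors of each query cell (reference-only, matching the purpose of
annotating new cells against a fixed reference) and assigns the modal
neighbor label. Ties are broken by the smaller mean distance to the
tied label's neighbors, then lexicographically — a deterministic
two-stage rule chosen because majority vote alone under-specifies the
answer.

## Fusion and ITD detection

A breakpoint is described by its two flanks; `build_junction_kmer()`
derives the k-mer spanning it (k = 12 by default, the odd-k extra base
taken upstream). A read supports a junction when the k-mer — or its
reverse complement, since cDNA reads arrive in either orientation —
occurs within it; matching is exact by default, with a sliding Hamming
comparison available for mismatch tolerance. Wild-type reads never
cross the breakpoint, so they cannot contain the k-mer. The FLT3
internal tandem duplication is handled as just another junction whose
k-mer spans the novel sequence created by the insertion boundary.
`call_positive_cells()` flags a cell when its supporting count strictly
exceeds 3 (i.e. ≥ 4 reads). Raw read counts are the default positivity
currency; UMI-deduplicated molecule counts are always reported and can
drive the call instead (`use_umi = TRUE`), since whether the published
rule preceded or followed deduplication is not documented.

## Deconvolution

`build_signature()` downsamples annotated cells uniformly (default cap
10,000), finds one-vs-rest markers per population, and stores each
population's mean **linear** CPM over the marker union. Linear scale is
essential: a bulk profile is then (approximately) linear in cell
proportions, which is the premise of the regression below.

`svr_deconvolve()` mirrors the established support-vector-regression
deconvolution recipe: restrict to signature genes present in the bulk
table, drop genes constant across the cohort, z-standardize the
signature matrix (as a whole) and each mixture vector, fit linear-kernel
ν-SVR for ν ∈ {0.25, 0.5, 0.75} with cost 1, and keep the lowest-RMSE
fit. The ν grid, kernel and cost follow the published conventions of
that recipe, since "SVR" alone under-determines them. Standardizing the
mixture makes fractions invariant to the overall scale of the bulk
sample (asserted numerically in the tests). Negative coefficients are
clipped to zero and renormalized into fractions; the raw signed
coefficients are kept alongside because calibration operates on them.

`calibrate()` fits, per population, ordinary least squares of the
observed single-cell proportion on the raw SVR coefficient across
paired samples (≥ 3 required). Observed proportions are computed among
cells assigned to the nine signature populations only and renormalized
— the signature deliberately omits monocytes/DCs, and leaving them in
would break row-sum comparability between the two sides of the
regression. `predict_proportions()` applies the per-population line to
a cohort and clips to [0, 1].

`loo_validate()` is the honesty check: for each paired sample in turn
it rebuilds the signature and calibration without that sample, predicts
the held-out composition, and scores the fold by Pearson's R between
predicted and observed proportions **across populations** within the
held-out sample (the across-samples-per-population alternative is a
different question — cohort-level tracking of one population — and is
what the deconvolution benchmark measures for the stem-like branch).
The summary reports the median fold R and a 2.5–97.5 percentile
interval across folds; the interval construction is a package choice,
as the published analysis does not state how its confidence interval
was derived.

## The stemness score

`apl_stemness_panel()` ships the published 11-gene panel (SKAP2,
IL1RAP, PLD1, HOPX, TRIM47, MAP2K1, TNFSF4, OLFML2A, P2RY14, NPTX2,
RALA). `stemness_score()` averages log2(TPM+1) over the panel genes
present; "mean expression" without a stated scale is dimensionally
unstable across cohorts, and log2(TPM+1) is the conventional choice —
it is configuration, not dogma. Genes weigh equally: coefficients for
the published panel were never printed, and "mean expression level"
implies equal weighting. Missing panel genes are excluded with a
warning carrying the count, rather than failing, because cohort
annotations differ; the count is also in the output table.

The construction route is implemented end to end for synthetic
validation: `select_candidates()` builds the quantity-driven set (genes
passing stem-vs-other-branches thresholds while detected in at most 10%
of non-stem cells — "exclusively expressed") and the quality-driven set
(significant stem-vs-HSPC DEGs), with the quality set as the default
pool; `label_top_decile()` marks the top 10% of samples by estimated
stem-like proportion (boundary ties all positive, both classes must be
non-empty); `fit_lasso_panel()` runs L1-penalized **logistic**
regression — top-decile separation defines a binary outcome, and the
published description does not state the family — with the penalty
chosen by 10-fold cross-validated deviance minimum (the
one-standard-error rule is a flag). The exact published route from
candidate pool to the 11 genes (single fit vs. stability selection,
fold seed, λ rule) is not recoverable, so the published panel is
shipped as a constant and the construction machinery is validated by
driver-recovery simulations instead.

## Survival machinery

`logrank_test()` accumulates the standard hypergeometric
observed/expected/variance decomposition over event times and reports
the 1-df chi-square; it is implemented in-package because the cutoff
search below needs the standardized statistic at every candidate split,
and is cross-checked in the tests against `survival::survdiff` and a
brute-force oracle, including a fully hand-derived 6-subject table.
`km_curve()` delegates to `survival::survfit` (product-limit estimate,
Greenwood errors).

`maxstat_cutoff()` evaluates |O − E|/√V at every distinct score within
the 10–90% quantile range (candidates leaving a group empty are
skipped) and returns the maximizing cutoff, smallest on ties; the high
group is score > cutoff. No small-sample correction is applied to the
maximal statistic: the cutoff is the deliverable, and the p-value
subsequently computed at that cutoff by `logrank_test()` is optimistic
— a caveat users should carry to any survival figure built this way.

The cutoff-recovery benchmark (`benchmark_maxstat_recovery()`) plants a
hazard step (ratio 4, n = 200) at c0 = 0.475 and asks whether the
recovered cutoff lies within the two observed scores bracketing c0.
Scores are drawn on a 0.05 grid — 41 levels with ties, as for any score
reported at fixed precision — a deliberate design choice: with fully
continuous scores the bracketing interval between adjacent order
statistics is a single rank wide, and oracle simulations show the
argmax lands exactly there only about half the time even at hazard
ratio 4 (while being within about three subjects of the true boundary
in ~90% of replicates). Tied scores give the bracket non-trivial width,
making "recovered the true partition" a well-posed event; with the grid
design the recovery rate is measured by the benchmark itself.

## The synthetic-data module

Everything above is validated on data from `make_population_profiles()`
and its companions, which emulate: population-specific marker programs
(disjoint marker sets elevated `effect_size`-fold over a shared
baseline with mild lognormal gene-to-gene wobble), overdispersed UMI
counts (negative binomial with one shared dispersion, default 0.3 —
the simplest model matching single-cell overdispersion, configurable),
per-cell mitochondrial content (a Beta(2, 38) share, mean 5%, routed
through `MT-`-prefixed genes so the QC rule is exercised by name, as in
real pipelines), pseudobulk mixtures (expectation mode with analytic
truth, or cell-resampling mode with sampling-noise truth — the
benchmarking relation between bulk and single-cell data is not
specified anywhere, so both are first-class), targeted reads with
planted junction k-mers at random offsets (background reads are
rejection-sampled to guarantee zero junction content, so error-free
truth tables are exact), and exponential survival with hazard
baseline × exp(β·score), independent uniform censoring and optional
administrative truncation.

What the generator does **not** emulate — and hence what passing tests
do not establish — includes doublets, ambient RNA, batch effects,
gene–gene correlation beyond the population structure, isoform
complexity and sequencing-depth gradients. All distributional choices
are stand-ins stated here as configuration, not claims about any real
dataset.

Reference study conditions used by the benchmarks and acceptance tests:
2000 genes, 9 populations, 40 markers each at effect 8 for
deconvolution (120 cells per population for the signature; 20 Dirichlet
pseudobulk samples with stem-like mean 5% and log-noise 0.1); 12
noise-free paired samples of ~360 cells for leave-one-out (signature
downsample 1800 per fold, keeping the 12-fold rebuild affordable on one
CPU); 3 populations with 300 reference + 100 query cells each for label
transfer; 15 drivers among 900 candidates at n = 300 over 20 seeds for
panel recovery; n = 100 over 1000 replicates for log-rank type-I error
and n = 200 over 100 replicates for cutoff recovery. These sizes are
the package's chosen compromise between statistical resolution and a
laptop-scale runtime.

## Numerical details and degenerate inputs

- Zero-total cells make CPM undefined: `normalize_cpm()` errors naming
  the offending barcode rather than producing NaNs.
- Wilcoxon variance uses the tie-corrected formula; a gene with a
  degenerate rank variance gets p = 1.
- SVR standardization divides by the whole-signature standard
  deviation; constant mixtures and cohorts with too few non-constant
  signature genes (< 50 shared) are errors, not warnings.
- If every SVR coefficient of a sample clips to zero, fractions fall
  back to uniform rather than 0/0.
- `maxstat_cutoff()` skips candidates with zero log-rank variance and
  errors only if none remain; `which.max` returns the first maximum, so
  ties resolve to the smallest cutoff.
- All generators run under `withr::with_seed`, so they are pure
  functions of their arguments and never disturb the caller's RNG
  state; `run_pipeline()` derives each stage's seed from the global
  seed by a fixed affine map, keeping partial reruns reproducible.

## Known limitations

The calibration model is per-population univariate; cross-population
leakage in the SVR coefficients is absorbed only insofar as it is
linear in the paired cohort. The LOO interval is a percentile interval
over 12 folds and should be read as descriptive. Fusion detection takes
junction sequences as inputs — there is no breakpoint discovery, no
alignment, and no attempt to quantify isoform usage. The survival
module stops at log-rank stratification; proportional-hazards modeling
of covariates is out of scope. Absolute cell abundances are not
estimated, only relative proportions.
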
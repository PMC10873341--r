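# aplstem

Quantifying leukemic stem-like cells in acute promyelocytic leukemia (APL)
from bulk and single-cell transcriptomes.

APL blasts form a differentiation hierarchy rooted in a rare stem-like
population whose abundance carries prognostic information — notably for
early death, the main cause of treatment failure in an otherwise highly
curable leukemia. Estimating that abundance from routine bulk RNA-seq
requires (i) a single-cell-derived signature of the blast branches and
(ii) a deconvolution model calibrated against samples where the true
cellular composition is known. `aplstem` implements that workflow as a
tested, reusable R package, together with the surrounding machinery: QC
and marker detection for single-cell matrices, KNN label transfer for
annotating new cells against a reference, junction k-mer detection of
PML/RARα fusion and FLT3-ITD transcripts in barcoded targeted reads, an
11-gene stemness score, and survival stratification by a maximally
selected log-rank cutoff. A synthetic-data module generates every input
with recorded ground truth, so the full pipeline runs and is validated
without access to patient data.

## Methods at a glance

- **Signature matrix.** From annotated cells, one-vs-rest markers per
  population are found by Wilcoxon rank-sum tests on CPM expression
  (log₂FC > 0.58, detection fraction > 0.1, BH-adjusted *P* < 0.05); the
  signature **S** (genes × 9 populations: six APL branches — stem-like,
  Prog-like, GMP-like, cycling GMP-like, S100hiGMP-like, MDP-like — plus
  T/NK, B, erythroid) holds each population's mean linear CPM over the
  marker union.
- **Deconvolution.** For a bulk TPM profile **y**, restrict to signature
  genes, z-standardize **S** and **y**, and fit linear-kernel ν-support
  vector regression **y** ≈ **S β** for ν ∈ {0.25, 0.5, 0.75}, keeping
  the lowest-RMSE fit. Negative coefficients are clipped and the rest
  renormalized into fractions.
- **Calibration.** Over samples with paired single-cell data, each
  population's observed proportion is regressed on its raw SVR
  coefficient (ordinary least squares); the fitted line maps cohort
  coefficients to calibrated proportions, clipped to [0, 1]. A
  leave-one-out harness rebuilds signature and calibration without each
  sample in turn and scores the held-out prediction by Pearson's R
  across populations.
- **Stemness score.** The mean of log₂(TPM + 1) over an 11-gene panel
  (*SKAP2, IL1RAP, PLD1, HOPX, TRIM47, MAP2K1, TNFSF4, OLFML2A, P2RY14,
  NPTX2, RALA*). Panel construction from scratch is also implemented:
  candidate genes from stem-like differential expression, samples
  labeled by top-decile estimated stem-like proportion, and an
  L1-penalized logistic regression with 10-fold cross-validated penalty
  choosing the panel.
- **Survival.** Two-group log-rank test from the per-event-time
  hypergeometric O/E/V decomposition; cutoff selection by the maximally
  selected standardized log-rank statistic over the 10–90% score
  quantiles; Kaplan–Meier curves with Greenwood errors.
- **Fusion/ITD calling.** A 12-bp k-mer spanning the breakpoint
  (or ITD insertion boundary) is scanned against barcoded reads on both
  strands; a cell is called positive with **more than three** supporting
  reads (UMI-deduplicated counts optional).

## Worked example

```r
library(aplstem)
library(dplyr)

profiles <- make_population_profiles(n_genes = 1000, markers_per_pop = 30,
                                     effect_size = 8, seed = 1)
cells <- simulate_cells(profiles, cells_per_pop = 100, seed = 2)
qc <- qc_filter(cells$matrix)
qc$report[, c("n_input_cells", "n_removed_mito", "n_retained")]
#> # A tibble: 1 × 3
#>   n_input_cells n_removed_mito n_retained
#>           <int>          <int>      <int>
#> 1           900             91        809

sig <- build_signature(qc$matrix, downsample = 10000, seed = 3)
sig
#> <signature_matrix> 270 genes x 9 populations

props <- dirichlet_proportions(12, 9, alpha = c(1, rep(19/8, 8)), seed = 4)
colnames(props) <- apl_populations()
bulk <- simulate_pseudobulk(profiles, props, noise_sd = 0.1, seed = 5)

dec  <- svr_deconvolve(bulk$bulk, sig)
cal  <- calibrate(dec, bulk$truth)
pred <- predict_proportions(bulk$bulk, sig, cal)

stem <- pred |> filter(population == "stem-like") |>
  left_join(bulk$truth, by = c("sample_id", "population"))
stem |> select(sample_id, raw_coefficient, calibrated_proportion, proportion)
#> # A tibble: 12 × 4
#>   sample_id raw_coefficient calibrated_proportion proportion
#>   <chr>               <dbl>                 <dbl>      <dbl>
#> 1 PB01              0.0826                0.0281     0.0297
#> 2 PB02              0.0260                0.0137     0.00795
#> 3 PB03              0.00498               0.00830    0.00945
#> 4 PB04              0.448                 0.121      0.101
#> 5 PB05              0.216                 0.0621     0.0709
#> # ...

cor(stem$calibrated_proportion, stem$proportion)
#> [1] 0.985
```

The twelve pseudobulk samples were mixed with known proportions
(stem-like averaging ~5% of cells); after SVR deconvolution and linear
calibration, the predicted stem-like proportions track the truth with
R ≈ 0.99. `stemness_score()` then turns any bulk TPM table into the
11-gene score, `maxstat_cutoff()` finds the score threshold maximizing
the standardized log-rank statistic, and `logrank_test()` /
`km_curve()` (with `autoplot()`) compare the resulting high/low groups.
`run_pipeline()` chains all stages on synthetic data and writes TSV
artifacts plus a manifest of every seed and parameter used.

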
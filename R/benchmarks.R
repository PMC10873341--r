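#' Benchmark scenarios with known ground truth
#'
#' Each `benchmark_*()` function builds a synthetic dataset under the
#' package's reference study conditions, runs the corresponding pipeline
#' stage, and returns the headline metric(s) as a one-row tibble. They
#' are deterministic given `seed` and are what the reproduction script
#' and the acceptance tests run.
#'
#' @name benchmarks
NULL

#' @describeIn benchmarks Deconvolution recovery: 9 populations, 2000
#'   genes, 40 markers each at 8-fold effect; signature built from
#'   simulated annotated cells; 20 pseudobulk samples with Dirichlet
#'   proportions (stem-like mean 5%) and lognormal noise sd 0.1.
#'   Reports the Pearson correlation between true and estimated
#'   stem-like fractions, and (when `pracma` is available) the maximum
#'   absolute difference from a non-negative least-squares oracle on
#'   three noise-free mixtures.
#' @param seed Integer seed.
#' @param cells_per_pop Cells simulated per population for the signature.
#' @export
benchmark_deconvolution <- function(seed = 1L, cells_per_pop = 120) {
  prof <- make_population_profiles(n_genes = 2000, markers_per_pop = 40,
                                   effect_size = 8, seed = seed)
  sc <- simulate_cells(prof, cells_per_pop, seed = seed + 1L)
  sig <- suppressWarnings(build_signature(sc$matrix, downsample = 1e6,
                                          seed = seed + 2L))
  P <- dirichlet_proportions(20, 9, alpha = stem_weighted_alpha(apl_populations()),
                             seed = seed + 3L)
  colnames(P) <- apl_populations()
  pb <- simulate_pseudobulk(prof, P, noise_sd = 0.1, seed = seed + 4L)
  dec <- svr_deconvolve(pb$bulk, sig)
  j <- dec |>
    left_join(pb$truth, by = c("sample_id", "population")) |>
    filter(.data$population == "stem-like")
  stem_r <- cor(j$fraction, j$proportion)

  nnls_max_diff <- NA_real_
  if (requireNamespace("pracma", quietly = TRUE)) {
    P0 <- matrix(0, nrow = 3, ncol = 9,
                 dimnames = list(c("m1", "m2", "m3"), apl_populations()))
    P0["m1", 1:2] <- c(0.6, 0.4)
    P0["m2", c(1, 5)] <- c(0.3, 0.7)
    P0["m3", ] <- rep(1 / 9, 9)
    pb0 <- simulate_pseudobulk(prof, P0, noise_sd = 0, seed = seed + 5L)
    dec0 <- svr_deconvolve(pb0$bulk, sig)
    S <- sig$values
    diffs <- vapply(rownames(P0), function(s) {
      nn <- pracma::lsqnonneg(S, pb0$bulk[rownames(S), s])$x
      nn <- nn / sum(nn)
      est <- dec0 |> filter(.data$sample_id == s) |>
        arrange(match(.data$population, colnames(S))) |> pull(.data$fraction)
      max(abs(est - nn))
    }, 0)
    nnls_max_diff <- max(diffs)
  }
  tibble(stemlike_pearson_r = stem_r, nnls_max_abs_diff = nnls_max_diff,
         n_samples = nrow(P), n_signature_genes = nrow(sig$values))
}

#' @describeIn benchmarks Leave-one-out validation on 12 noise-free
#'   paired samples (expectation-mode pseudobulk at each sample's exact
#'   cell-count proportions). Reports fold count and median per-fold
#'   Pearson R across populations.
#' @param n_samples Number of paired samples (default 12).
#' @export
benchmark_loo <- function(seed = 1L, n_samples = 12) {
  prof <- make_population_profiles(n_genes = 2000, markers_per_pop = 40,
                                   effect_size = 8, seed = seed)
  pops <- apl_populations()
  P <- dirichlet_proportions(n_samples, 9, alpha = stem_weighted_alpha(pops),
                             seed = seed + 1L)
  colnames(P) <- pops
  ids <- sprintf("P%02d", seq_len(n_samples))
  cells <- list(); bulks <- list()
  for (i in seq_len(n_samples)) {
    n_per <- setNames(pmax(4L, round(P[i, ] * 360)), pops)
    sc <- simulate_cells(prof, n_per, sample_id = ids[i], seed = seed + 10L + i)
    cells[[ids[i]]] <- sc$matrix
    obs <- matrix(n_per / sum(n_per), nrow = 1,
                  dimnames = list(ids[i], pops))
    bulks[[i]] <- simulate_pseudobulk(prof, obs, noise_sd = 0,
                                      seed = seed + 50L + i)$bulk
  }
  bulk <- do.call(cbind, bulks)
  rep <- loo_validate(cells, bulk, downsample = 1800, seed = seed + 2L)
  tibble(n_folds = rep$summary$n_folds, median_fold_r = rep$summary$median_r,
         min_fold_r = min(rep$folds$pearson_r))
}

#' @describeIn benchmarks Fusion/ITD calling on an error-free planted
#'   simulation with boundary cases at 3 and 4 supporting reads.
#'   Reports whether per-cell counts equal the generator truth exactly,
#'   and the sensitivity and specificity of the "more than three reads"
#'   rule against the planted positives.
#' @export
benchmark_fusion <- function(seed = 1L) {
  jf <- build_junction_kmer("TCCGAATGGCAGGTCGATCCGGAACTGCAGG",
                            "TCAGTGGATCCGAGGCTTACGGATCAGCTAA",
                            name = "PML-RARA-L")
  ji <- build_junction_kmer("CAGTTTGGCATCACCGCGGAAT",
                            "GGAATCGCAGTACCTTAGGCTA", name = "FLT3-ITD")
  bcs <- sprintf("BC%03d", 1:40)
  pos <- list(
    "PML-RARA-L" = setNames(c(10L, 6L, 5L, 4L, 4L, 3L, 2L, 1L), bcs[1:8]),
    "FLT3-ITD" = setNames(c(7L, 4L, 3L, 1L), bcs[c(2, 11, 12, 13)]))
  sim <- simulate_targeted_reads(list(jf, ji), bcs, pos,
                                 background_reads_per_cell = 2,
                                 error_rate = 0, seed = seed)
  tab <- scan_reads(sim$reads, list(jf, ji))
  j <- tab |> left_join(sim$truth, by = c("barcode", "junction"))
  counts_exact <- all(j$supporting_read_count == j$planted_reads)
  calls <- call_positive_cells(tab, threshold = 3)
  called <- calls$positive[match(paste(j$barcode, j$junction),
                                 paste(calls$barcode, calls$junction))]
  truth_pos <- j$planted_reads > 3L
  tibble(counts_equal_truth = counts_exact,
         sensitivity = sum(called & truth_pos) / sum(truth_pos),
         specificity = sum(!called & !truth_pos) / sum(!truth_pos),
         n_cells = length(bcs))
}

#' @describeIn benchmarks KNN label transfer: 3 populations at 8-fold
#'   marker effect, 300 reference and 100 query cells per population,
#'   k = 50. Reports transfer accuracy against the recorded labels and
#'   whether a repeat run is identical.
#' @export
benchmark_knn <- function(seed = 1L) {
  prof <- make_population_profiles(n_genes = 600, populations = c("A", "B", "C"),
                                   markers_per_pop = 30, effect_size = 8,
                                   seed = seed)
  ref <- simulate_cells(prof, 300, sample_id = "ref", seed = seed + 1L)
  qry <- simulate_cells(prof, 100, sample_id = "qry", seed = seed + 2L)
  emb <- build_joint_embedding(ref$matrix, qry$matrix, n_hvg = 300, n_dims = 20)
  tr <- knn_transfer(emb, k = 50)
  truth <- qry$truth$label[match(tr$cell_id, qry$truth$barcode)]
  tr2 <- knn_transfer(emb, k = 50)
  tibble(accuracy = mean(tr$predicted_label == truth),
         deterministic = identical(tr$predicted_label, tr2$predicted_label),
         n_query = nrow(tr))
}

#' @describeIn benchmarks LASSO panel recovery: 15 driver genes among
#'   900 candidates, 300 samples (10% positive), driver effect 2 on the
#'   log scale, repeated over `n_rep` seeds. Reports mean selection
#'   precision against the planted drivers.
#' @param n_rep Number of repeated fits.
#' @export
benchmark_lasso <- function(seed = 1L, n_rep = 20) {
  prec <- vapply(seq_len(n_rep), function(i) {
    s <- seed + i
    withr::with_seed(s, {
      n <- 300; p <- 900; k <- 15
      y <- integer(n)
      y[sample(n, 30)] <- 1L  # top-decile-sized positive class
      X <- matrix(rnorm(n * p), nrow = p,
                  dimnames = list(sprintf("G%03d", seq_len(p)),
                                  sprintf("s%03d", seq_len(n))))
      X[seq_len(k), ] <- X[seq_len(k), ] + 2 * rep(y, each = k)
    })
    fit <- fit_lasso_panel(X, y, seed = s)
    if (length(fit$selected_genes) == 0) return(NA_real_)
    mean(fit$selected_genes %in% sprintf("G%03d", seq_len(15)))
  }, 0)
  tibble(mean_precision = mean(prec, na.rm = TRUE), n_rep = n_rep)
}

#' @describeIn benchmarks Type-I error of the log-rank test at a fixed
#'   median score cutoff under the null (no score effect), over `reps`
#'   simulated cohorts of size `n`.
#' @param n Cohort size per replicate.
#' @param reps Number of replicates.
#' @export
benchmark_logrank_type1 <- function(seed = 1L, n = 100, reps = 1000) {
  rej <- vapply(seq_len(reps), function(i) {
    sc <- withr::with_seed(seed + i, runif(n))
    surv <- simulate_survival(setNames(sc, sprintf("P%03d", seq_len(n))),
                              effect_beta = 0, baseline_rate = 0.1,
                              censor_rate = 0.1, seed = seed + 100000L + i)
    lr <- logrank_test(surv, surv$score > median(surv$score))
    lr$p_value < 0.05
  }, TRUE)
  tibble(type1_error = mean(rej), n = n, reps = reps)
}

#' @describeIn benchmarks Maxstat cutoff recovery: scores on a 0.05 grid
#'   (ties expected, as for any score reported at fixed precision), a
#'   planted hazard step (ratio 4) at c0 = 0.475 between grid points,
#'   n = 200 per replicate. Reports the fraction of replicates whose
#'   recovered cutoff lies within the two observed scores bracketing c0.
#' @export
benchmark_maxstat_recovery <- function(seed = 1L, n = 200, reps = 100) {
  c0 <- 0.475
  hits <- vapply(seq_len(reps), function(i) {
    sc <- withr::with_seed(seed + i, round(runif(n) * 20) / 20)
    step <- as.numeric(sc > c0)
    surv <- simulate_survival(setNames(step, sprintf("P%03d", seq_len(n))),
                              effect_beta = log(4), baseline_rate = 0.1,
                              censor_rate = 0, seed = seed + 200000L + i)
    ms <- maxstat_cutoff(sc, surv)
    lo <- max(sc[sc <= c0]); hi <- min(sc[sc > c0])
    ms$cutoff >= lo - 1e-12 && ms$cutoff <= hi + 1e-12
  }, TRUE)
  tibble(recovery_rate = mean(hits), n = n, reps = reps)
}

#' Hand-enumerable six-cell QC demonstration matrix
#'
#' A 404-gene, six-cell matrix in which one cell violates each QC rule
#' (299 detected genes; 450 total counts; 30,050 total counts; 12.3%
#' mitochondrial), one cell is clean, and one sits exactly on every
#' boundary (300 genes, 500 counts, 10.0% mito) and must be retained
#' under the strict exclusion semantics.
#'
#' @return A [gexp] with cells C1..C6; C5 and C6 survive [qc_filter()].
#' @export
qc_demo_matrix <- function() {
  n_genes <- 404
  genes <- c(sprintf("MT-%02d", 1:4), sprintf("G%03d", 5:n_genes))
  m <- matrix(0L, nrow = n_genes, ncol = 6,
              dimnames = list(genes, sprintf("C%d", 1:6)))
  m[5:303, 1] <- 3L
  m[5:304, 2] <- 1L; m[5:154, 2] <- 2L
  m[5:304, 3] <- 100L; m[5, 3] <- 150L
  m[5:304, 4] <- 2L; m[1:4, 4] <- 21L
  m[5:404, 5] <- 2L
  m[5:302, 6] <- 1L; m[304, 6] <- 152L; m[1, 6] <- 50L
  gexp(m)
}
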
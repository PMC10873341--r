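#' Default pipeline configuration
#'
#' All stage parameters with their defaults, plus a single global seed
#' from which every stage's seed is derived by a fixed offset (so
#' partial reruns reproduce exactly).
#'
#' @param seed Global seed.
#' @return Named list of stage settings.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_genes = 2000, markers_per_pop = 40, effect_size = 8,
                    cells_per_pop = 120, library_size = 5000, dispersion = 0.3,
                    n_samples = 12, noise_sd = 0),
    qc = list(min_genes = 300, min_counts = 500, max_counts = 30000,
              max_mito = 0.10),
    signature = list(downsample = 10000, logfc_min = 0.58, min_pct = 0.1,
                     alpha = 0.05),
    deconvolve = list(nu_grid = c(0.25, 0.5, 0.75)),
    score = list(panel = "default11"),
    survival = list(effect_beta = 2, baseline_rate = 0.1, censor_rate = 0.1,
                    quantile_range = c(0.10, 0.90))
  )
}

# fixed per-stage seed derivation from the global seed
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, qc = 211L, signature = 307L, deconvolve = 401L,
            score = 503L, survival = 601L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order on synthetic data:
#' `simulate` (profiles, cells, pseudobulk with known proportions) ->
#' `qc` -> `signature` -> `deconvolve` (with calibration) -> `score`
#' (stemness score of each bulk sample) -> `survival` (score-driven
#' outcomes, maxstat cutoff, log-rank test). Artifacts are written as
#' TSV/JSON under `out_dir`, together with a run manifest recording the
#' package version, every seed and parameter actually applied, and md5
#' hashes of the emitted files. Inputs on disk are never mutated; reruns
#' with an identical config are bit-identical.
#'
#' @param config A [default_config()]-shaped list.
#' @param stages Ordered subset of
#'   `c("simulate","qc","signature","deconvolve","score","survival")`.
#'   Each requested stage requires its predecessors in the same run.
#' @param out_dir Output directory (created).
#'
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "qc", "signature",
                                    "deconvolve", "score", "survival"),
                         out_dir = tempfile("aplstem_run_")) {
  all_stages <- c("simulate", "qc", "signature", "deconvolve", "score", "survival")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # dependency check before execution
  need <- all_stages[seq_len(max(match(stages, all_stages)))]
  missing_dep <- setdiff(need, stages)
  if (length(missing_dep) > 0) {
    abort(sprintf("stage '%s' requires earlier stage(s): %s.",
                  stages[which.max(match(stages, all_stages))],
                  paste(missing_dep, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  emitted <- character()
  log_lines <- character()
  log_it <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if ("simulate" %in% stages) {
    cf <- config$simulate; sd0 <- stage_seed(config$seed, "simulate")
    log_it("simulate: seed=%d n_genes=%d effect=%g", sd0, cf$n_genes, cf$effect_size)
    profiles <- make_population_profiles(
      n_genes = cf$n_genes, markers_per_pop = cf$markers_per_pop,
      effect_size = cf$effect_size, seed = sd0)
    sc <- simulate_cells(profiles, cells_per_pop = cf$cells_per_pop,
                         library_size = cf$library_size,
                         dispersion = cf$dispersion, seed = sd0 + 1L)
    props <- dirichlet_proportions(cf$n_samples, length(profiles$populations),
                                   seed = sd0 + 2L,
                                   alpha = stem_weighted_alpha(profiles$populations))
    colnames(props) <- profiles$populations
    pb <- simulate_pseudobulk(profiles, props, noise_sd = cf$noise_sd,
                              seed = sd0 + 3L)
    res$simulate <- list(profiles = profiles, cells = sc, pseudobulk = pb)
    write_mtx(sc$matrix, file.path(out_dir, "cells"))
    write_matrix_tsv(pb$bulk, file.path(out_dir, "pseudobulk_tpm.tsv"))
    readr::write_tsv(pb$truth, file.path(out_dir, "true_proportions.tsv"))
    readr::write_tsv(sc$truth, file.path(out_dir, "cell_labels.tsv"))
    emitted <- c(emitted, file.path(out_dir, c("pseudobulk_tpm.tsv",
                                               "true_proportions.tsv",
                                               "cell_labels.tsv")))
  }
  if ("qc" %in% stages) {
    cf <- config$qc
    log_it("qc: min_genes=%d min_counts=%d max_counts=%d max_mito=%g",
           cf$min_genes, cf$min_counts, cf$max_counts, cf$max_mito)
    qcd <- qc_filter(res$simulate$cells$matrix, min_genes = cf$min_genes,
                     min_counts = cf$min_counts, max_counts = cf$max_counts,
                     max_mito = cf$max_mito)
    res$qc <- qcd
    readr::write_tsv(as_tibble(qcd$report), file.path(out_dir, "qc_report.tsv"))
    emitted <- c(emitted, file.path(out_dir, "qc_report.tsv"))
  }
  if ("signature" %in% stages) {
    cf <- config$signature; sd0 <- stage_seed(config$seed, "signature")
    log_it("signature: seed=%d downsample=%d logfc_min=%g", sd0, cf$downsample,
           cf$logfc_min)
    sig <- build_signature(res$qc$matrix, downsample = cf$downsample,
                           seed = sd0, logfc_min = cf$logfc_min,
                           min_pct = cf$min_pct, alpha = cf$alpha)
    res$signature <- sig
    write_matrix_tsv(sig$values, file.path(out_dir, "signature_matrix.tsv"))
    emitted <- c(emitted, file.path(out_dir, "signature_matrix.tsv"))
  }
  if ("deconvolve" %in% stages) {
    cf <- config$deconvolve
    log_it("deconvolve: nu_grid=%s", paste(cf$nu_grid, collapse = ","))
    dec <- svr_deconvolve(res$simulate$pseudobulk$bulk, res$signature,
                          nu_grid = cf$nu_grid)
    obs <- res$simulate$pseudobulk$truth |>
      rename(proportion = "proportion")
    cal <- calibrate(dec, obs)
    pred <- predict_proportions(res$simulate$pseudobulk$bulk, res$signature, cal,
                                nu_grid = cf$nu_grid)
    res$deconvolve <- list(raw = dec, calibration = cal, predicted = pred)
    readr::write_tsv(pred, file.path(out_dir, "deconvolution.tsv"))
    readr::write_tsv(cal, file.path(out_dir, "calibration.tsv"))
    emitted <- c(emitted, file.path(out_dir, c("deconvolution.tsv", "calibration.tsv")))
  }
  if ("score" %in% stages) {
    log_it("score: panel=%s", config$score$panel)
    panel_markers <- res$signature$markers[["stem-like"]]
    panel <- if (identical(config$score$panel, "default11") &&
                 any(apl_stemness_panel()$gene_list %in%
                     rownames(res$simulate$pseudobulk$bulk))) {
      apl_stemness_panel()
    } else {
      head(panel_markers, 11)  # synthetic namespace: stem-like markers
    }
    sco <- stemness_score(res$simulate$pseudobulk$bulk, panel)
    res$score <- sco
    readr::write_tsv(sco, file.path(out_dir, "stemness_scores.tsv"))
    emitted <- c(emitted, file.path(out_dir, "stemness_scores.tsv"))
  }
  if ("survival" %in% stages) {
    cf <- config$survival; sd0 <- stage_seed(config$seed, "survival")
    log_it("survival: seed=%d beta=%g", sd0, cf$effect_beta)
    surv <- simulate_survival(setNames(res$score$score, res$score$sample_id),
                              effect_beta = cf$effect_beta,
                              baseline_rate = cf$baseline_rate,
                              censor_rate = cf$censor_rate, seed = sd0)
    cut <- maxstat_cutoff(surv$score, surv, quantile_range = cf$quantile_range)
    lr <- logrank_test(surv, surv$score > cut$cutoff)
    res$survival <- list(table = surv, cutoff = cut, logrank = lr)
    write_survival_tsv(surv, file.path(out_dir, "survival.tsv"))
    emitted <- c(emitted, file.path(out_dir, "survival.tsv"))
  }

  manifest <- list(
    package = "aplstem",
    version = as.character(utils::packageVersion("aplstem")),
    stages = stages,
    global_seed = config$seed,
    stage_seeds = lapply(setNames(nm = intersect(names(default_config()), stages)),
                         function(s) if (s %in% c("simulate", "signature", "survival"))
                           stage_seed(config$seed, s) else NA),
    config = config,
    log = log_lines,
    file_hashes = as.list(tools::md5sum(emitted)))
  write_config(manifest, file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Dirichlet mixture proportions
#'
#' @param n_samples Rows to draw.
#' @param n_pops Number of populations (columns).
#' @param alpha Dirichlet concentration, scalar or length `n_pops`.
#' @param seed Integer seed.
#' @return Matrix n_samples x n_pops, rows summing to 1.
#' @export
dirichlet_proportions <- function(n_samples, n_pops, alpha = 1, seed = 1L) {
  if (length(alpha) == 1) alpha <- rep(alpha, n_pops)
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * n_pops, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    sweep(g, 1, rowSums(g), "/")
  })
}

# concentration vector making the stem-like population a rare (~5% mean)
# fraction, as in the study's blast hierarchy
stem_weighted_alpha <- function(populations, total = 20) {
  a <- rep((total - 1) / (length(populations) - 1), length(populations))
  a[populations == "stem-like"] <- 1
  a
}
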
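#' Build a signature matrix from annotated single-cell data
#'
#' Cells are downsampled uniformly at random, one-vs-rest markers are
#' computed per population with [find_markers()], and the signature is
#' the per-population mean of *linear* CPM expression over the union of
#' marker sets — linear so a bulk mixture is linear in cell proportions.
#'
#' @param x An annotated [gexp] (labels in `cell_meta$label`).
#' @param populations Populations to include (default: all 9 study
#'   populations present in the labels).
#' @param downsample Cells to keep before marker detection (default
#'   10000); if larger than the cell count, all cells are used with a
#'   warning.
#' @param seed Seed for the downsample.
#' @param logfc_min,min_pct,alpha Marker significance settings passed to
#'   [find_markers()].
#'
#' @return A `signature_matrix`: list with `values` (signature genes x
#'   populations matrix of mean CPM), `markers` (named list), and
#'   `provenance`.
#' @export
build_signature <- function(x, populations = apl_populations(),
                            downsample = 10000, seed = 1L,
                            logfc_min = 0.58, min_pct = 0.1, alpha = 0.05) {
  stopifnot(inherits(x, "gexp"))
  labs <- x$cell_meta$label
  missing_pop <- setdiff(populations, unique(labs))
  if (length(missing_pop) > 0) {
    abort(paste0("population(s) absent from labels: ",
                 paste(missing_pop, collapse = ", ")))
  }
  keep <- x$cell_meta$barcode[labs %in% populations]
  x <- gexp_subset_cells(x, keep)
  if (downsample < ncol(x$counts)) {
    bc <- withr::with_seed(seed, sample(x$cell_meta$barcode, downsample))
    x <- gexp_subset_cells(x, bc)
  } else if (downsample > ncol(x$counts)) {
    warn(sprintf("downsample %d exceeds cell count %d; using all cells.",
                 downsample, ncol(x$counts)))
  }
  tab <- table(x$cell_meta$label)
  if (any(tab[populations] < 20)) {
    abort("every population needs >= 20 cells after downsampling.")
  }
  norm <- normalize_cpm(x)
  labs <- x$cell_meta$label
  markers <- map(setNames(populations, populations), function(p) {
    dt <- find_markers(norm, labs, group1 = p, group2 = "rest",
                       logfc_min = logfc_min, min_pct = min_pct, alpha = alpha)
    dt$gene[dt$passes_threshold]
  })
  sig_genes <- sort(unique(unlist(markers)))
  if (length(sig_genes) == 0) abort("no marker genes found for any population.")
  values <- vapply(populations, function(p) {
    Matrix::rowMeans(norm[sig_genes, labs == p, drop = FALSE])
  }, numeric(length(sig_genes)))
  rownames(values) <- sig_genes
  structure(list(values = values, markers = markers,
                 provenance = list(downsample = min(downsample, ncol(x$counts)),
                                   seed = seed,
                                   deg_settings = list(logfc_min = logfc_min,
                                                       min_pct = min_pct,
                                                       alpha = alpha))),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d populations\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# CIBERSORT-style single-mixture nu-SVR fit over a nu grid
svr_fit_one <- function(X, y, nu_grid) {
  ys <- (y - mean(y)) / sd(y)
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(X, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = 1, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    recon <- as.numeric(X %*% w)
    rmse <- sqrt(mean((recon - ys)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(nu = nu, w = w, rmse = rmse, corr = cor(recon, ys))
    }
  }
  best
}

#' Estimate population coefficients in bulk profiles by nu-SVR
#'
#' For each bulk sample: restrict to signature genes present in the bulk
#' table, drop genes with zero variance across the cohort, z-standardize
#' the signature matrix (as a whole) and the mixture vector, fit a
#' linear-kernel nu-support-vector regression for each nu in the grid,
#' and keep the fit with the lowest reconstruction RMSE. Negative
#' coefficients are clipped to zero and renormalized into fractions.
#'
#' @param bulk Genes x samples matrix (TPM or CPM scale) with gene
#'   rownames, or a tibble whose first column is the gene id.
#' @param signature A [build_signature()] result or a plain genes x
#'   populations matrix.
#' @param nu_grid Candidate nu values (default 0.25, 0.5, 0.75).
#' @param min_shared_genes Minimum signature genes that must be present
#'   in the bulk table (default 50).
#'
#' @return A `deconv_result` tibble: sample_id, population,
#'   raw_coefficient, fraction, chosen_nu, fit_rmse, fit_correlation.
#' @export
svr_deconvolve <- function(bulk, signature, nu_grid = c(0.25, 0.5, 0.75),
                           min_shared_genes = 50) {
  bulk <- as_bulk_matrix(bulk)
  S <- if (inherits(signature, "signature_matrix")) signature$values else signature
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) < min_shared_genes) {
    abort(sprintf("only %d signature genes present in bulk table (need >= %d).",
                  length(shared), min_shared_genes))
  }
  B <- bulk[shared, , drop = FALSE]
  keep <- apply(B, 1, function(v) var(v) > 0 | ncol(B) == 1)
  B <- B[keep, , drop = FALSE]
  S <- S[rownames(B), , drop = FALSE]
  if (nrow(B) < min_shared_genes) {
    abort("too few non-constant signature genes across the bulk cohort.")
  }
  Xs <- (S - mean(S)) / sd(as.vector(S))

  res <- map(colnames(bulk), function(sid) {
    y <- B[, sid]
    if (sd(y) == 0) abort(sprintf("mixture '%s' is constant.", sid))
    fit <- svr_fit_one(Xs, y, nu_grid)
    w <- pmax(fit$w, 0)
    frac <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    tibble(sample_id = sid, population = colnames(S),
           raw_coefficient = fit$w, fraction = frac,
           chosen_nu = fit$nu, fit_rmse = fit$rmse, fit_correlation = fit$corr)
  })
  out <- bind_rows(res)
  structure(out, class = c("deconv_result", class(out)))
}

as_bulk_matrix <- function(bulk) {
  if (is.data.frame(bulk)) {
    m <- as.matrix(bulk[, -1, drop = FALSE])
    rownames(m) <- as.character(bulk[[1]])
    m
  } else {
    as.matrix(bulk)
  }
}

#' Observed population proportions from annotated cells
#'
#' Per-sample cell-count fractions among cells assigned to the given
#' populations only (others are excluded and the fractions renormalized,
#' keeping them comparable with the 9-population signature).
#'
#' @param cell_meta Tibble with `sample_id` and `label` columns (for
#'   example a [gexp]'s `cell_meta`).
#' @param populations Populations to keep.
#'
#' @return Tibble: sample_id, population, proportion (rows sum to 1 per
#'   sample).
#' @export
observed_proportions <- function(cell_meta, populations = apl_populations()) {
  cell_meta |>
    filter(.data$label %in% populations) |>
    count(.data$sample_id, .data$label) |>
    group_by(.data$sample_id) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    select(sample_id = "sample_id", population = "label", proportion = "proportion") |>
    tidyr::complete(.data$sample_id, population = populations,
                    fill = list(proportion = 0)) |>
    select(-dplyr::any_of("n"))
}

#' Calibrate SVR coefficients against observed proportions
#'
#' Ordinary least squares per population of the observed single-cell
#' proportion on the raw SVR coefficient over paired samples, giving the
#' linear map used by [predict_proportions()].
#'
#' @param results A [svr_deconvolve()] result over the paired samples.
#' @param observed Tibble sample_id, population, proportion (e.g. from
#'   [observed_proportions()]).
#'
#' @return A `calibration_model` tibble: population, slope, intercept,
#'   pearson_r, n_samples.
#' @export
calibrate <- function(results, observed) {
  paired <- results |>
    select("sample_id", "population", "raw_coefficient") |>
    dplyr::inner_join(observed, by = c("sample_id", "population"))
  n_s <- dplyr::n_distinct(paired$sample_id)
  if (n_s < 3) abort("calibration needs >= 3 paired samples.")
  out <- paired |>
    group_by(.data$population) |>
    summarise(slope = {
      if (sd(.data$raw_coefficient) == 0)
        abort(sprintf("zero-variance coefficients for population '%s'.",
                      .data$population[1]))
      cov(.data$raw_coefficient, .data$proportion) / var(.data$raw_coefficient)
    },
    intercept = mean(.data$proportion) -
      cov(.data$raw_coefficient, .data$proportion) /
      var(.data$raw_coefficient) * mean(.data$raw_coefficient),
    pearson_r = cor(.data$raw_coefficient, .data$proportion),
    n_samples = dplyr::n(), .groups = "drop")
  structure(out, class = c("calibration_model", class(out)))
}

#' Predict calibrated proportions for a bulk cohort
#'
#' Runs [svr_deconvolve()] and maps each population's raw coefficient
#' through its calibration line, clipping the result to `[0, 1]`.
#'
#' @param bulk Genes x samples TPM table.
#' @param signature A [build_signature()] result.
#' @param calibration A [calibrate()] result.
#' @param ... Passed to [svr_deconvolve()].
#'
#' @return A `deconv_result` tibble with an added `calibrated_proportion`
#'   column.
#' @export
predict_proportions <- function(bulk, signature, calibration, ...) {
  S <- if (inherits(signature, "signature_matrix")) signature$values else signature
  if (!all(calibration$population %in% colnames(S))) {
    abort("calibration populations must be a subset of signature populations.")
  }
  res <- svr_deconvolve(bulk, signature, ...)
  out <- res |>
    left_join(select(calibration, "population", "slope", "intercept"),
              by = "population") |>
    mutate(calibrated_proportion = pmin(1, pmax(0,
      .data$slope * .data$raw_coefficient + .data$intercept))) |>
    select(-"slope", -"intercept")
  structure(out, class = c("deconv_result", class(out)))
}

#' Leave-one-out validation of the deconvolution model
#'
#' For each paired sample in turn: rebuild the signature from the
#' training samples' cells, deconvolve the training bulk profiles, fit
#' the calibration, predict the held-out sample's proportions, and score
#' the fold by the Pearson correlation between predicted and observed
#' proportions across populations. Folds whose training data lose a
#' population entirely are skipped with a warning.
#'
#' @param cells Named list of annotated [gexp] objects, one per sample.
#' @param bulk Genes x samples matrix whose column names match
#'   `names(cells)`.
#' @param populations Populations to deconvolve.
#' @param downsample,seed,... Passed to [build_signature()].
#'
#' @return An `loo_report`: list with `folds` (tibble sample_id,
#'   pearson_r, predicted/observed stem-like proportion), `summary`
#'   (median R and a 2.5-97.5 percentile interval across folds).
#' @export
loo_validate <- function(cells, bulk, populations = apl_populations(),
                         downsample = 10000, seed = 1L, ...) {
  stopifnot(is.list(cells), !is.null(names(cells)))
  bulk <- as_bulk_matrix(bulk)
  ids <- names(cells)
  if (!all(ids %in% colnames(bulk))) abort("every sample needs a bulk column.")
  if (length(ids) < 4) abort("leave-one-out needs >= 4 paired samples.")

  folds <- map(ids, function(held) {
    train <- setdiff(ids, held)
    pooled <- pool_gexp(cells[train])
    if (!all(populations %in% unique(pooled$cell_meta$label))) {
      warn(sprintf("fold '%s' skipped: training set misses a population.", held))
      return(NULL)
    }
    sig <- build_signature(pooled, populations, downsample = downsample,
                           seed = seed, ...)
    obs_train <- observed_proportions(pooled$cell_meta, populations)
    dec_train <- svr_deconvolve(bulk[, train, drop = FALSE], sig)
    cal <- calibrate(dec_train, obs_train)
    pred <- predict_proportions(bulk[, held, drop = FALSE], sig, cal)
    obs_held <- observed_proportions(cells[[held]]$cell_meta, populations)
    j <- pred |>
      left_join(obs_held, by = c("sample_id", "population"))
    tibble(sample_id = held,
           pearson_r = cor(j$calibrated_proportion, j$proportion),
           predicted_stem = j$calibrated_proportion[j$population == "stem-like"],
           observed_stem = j$proportion[j$population == "stem-like"])
  })
  folds <- bind_rows(folds)
  structure(list(
    folds = folds,
    summary = tibble(n_folds = nrow(folds),
                     median_r = median(folds$pearson_r),
                     ci_lower = unname(quantile(folds$pearson_r, 0.025)),
                     ci_upper = unname(quantile(folds$pearson_r, 0.975)))),
    class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<loo_report> %d folds, median R = %.3f [%.3f, %.3f]\n",
              s$n_folds, s$median_r, s$ci_lower, s$ci_upper))
  invisible(x)
}

# concatenate gexp objects over cells (shared gene set required)
pool_gexp <- function(xs) {
  g <- rownames(xs[[1]]$counts)
  for (x in xs) stopifnot(identical(rownames(x$counts), g))
  counts <- do.call(cbind, map(xs, "counts"))
  meta_cols <- Reduce(intersect, map(xs, ~ names(.x$cell_meta)))
  drop <- c("n_genes_detected", "total_counts", "mito_fraction")
  meta <- bind_rows(map(xs, ~ .x$cell_meta[, setdiff(meta_cols, drop)]))
  gexp(counts, meta)
}
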
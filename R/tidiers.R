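#' Tidy a calibration model
#'
#' @param x A [calibrate()] result.
#' @param ... Unused.
#' @return Tibble: population, slope, intercept, pearson_r, n_samples.
#' @export
tidy.calibration_model <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a fitted stemness model: one row per selected gene
#'
#' @param x A [fit_lasso_panel()] result.
#' @param ... Unused.
#' @return Tibble: gene, coefficient.
#' @export
tidy.stemness_model <- function(x, ...) {
  tibble(gene = x$selected_genes, coefficient = unname(x$coefficients))
}

#' One-row model summary for a stemness model
#'
#' @param x A [fit_lasso_panel()] result.
#' @param ... Unused.
#' @return Tibble: n_genes, lambda, lambda_rule, cv_folds, family.
#' @export
glance.stemness_model <- function(x, ...) {
  tibble(n_genes = length(x$selected_genes), lambda = x$lambda,
         lambda_rule = x$lambda_rule, cv_folds = x$cv_folds, family = x$family)
}

#' Tidy a log-rank result: per-group observed and expected events
#'
#' @param x A [logrank_test()] result.
#' @param ... Unused.
#' @export
tidy.logrank_result <- function(x, ...) x$groups

#' One-row summary of a log-rank test
#'
#' @param x A [logrank_test()] result.
#' @param ... Unused.
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value)
}

#' Tidy a maxstat cutoff search: the candidate profile
#'
#' @param x A [maxstat_cutoff()] result.
#' @param ... Unused.
#' @export
tidy.cutoff_result <- function(x, ...) x$candidates

#' One-row summary of a maxstat cutoff search
#'
#' @param x A [maxstat_cutoff()] result.
#' @param ... Unused.
#' @export
glance.cutoff_result <- function(x, ...) {
  tibble(cutoff = x$cutoff,
         max_standardized_statistic = x$max_standardized_statistic,
         search_lower = x$search_range[1], search_upper = x$search_range[2])
}

#' Tidy an LOO report: one row per fold
#'
#' @param x A [loo_validate()] result.
#' @param ... Unused.
#' @export
tidy.loo_report <- function(x, ...) x$folds

#' One-row summary of an LOO report
#'
#' @param x A [loo_validate()] result.
#' @param ... Unused.
#' @export
glance.loo_report <- function(x, ...) x$summary

#' Tidy a signature matrix into long form
#'
#' @param x A [build_signature()] result.
#' @param ... Unused.
#' @return Tibble: gene, population, mean_expression.
#' @export
tidy.signature_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE))
  names(out) <- c("gene", "population", "mean_expression")
  out
}
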
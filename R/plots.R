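#' Plot Kaplan-Meier curves
#'
#' Step plot of the product-limit estimate, one line per group, with
#' censoring marks.
#'
#' @param object A [km_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (!"group" %in% names(df)) df$group <- "all"
  anchor <- df |> group_by(.data$group) |>
    summarise(time = 0, estimate = 1, .groups = "drop")
  ggplot2::ggplot(bind_rows(anchor, df),
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(df, .data$n_censor > 0), shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated population fractions per sample
#'
#' Stacked bars of deconvolved fractions (or calibrated proportions when
#' present).
#'
#' @param object A [svr_deconvolve()] / [predict_proportions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconv_result <- function(object, ...) {
  y <- if ("calibrated_proportion" %in% names(object)) "calibrated_proportion"
       else "fraction"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id,
                                       y = .data[[y]],
                                       fill = .data$population)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot the maxstat candidate profile
#'
#' Standardized log-rank statistic against candidate cutoff, with the
#' selected cutoff marked.
#'
#' @param object A [maxstat_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cutoff_result <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutoff, y = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "Candidate cutoff",
                  y = "Standardized log-rank statistic") +
    ggplot2::theme_minimal()
}

#' Plot calibration fits
#'
#' Observed single-cell proportion against raw SVR coefficient per
#' population, with the per-population regression line.
#'
#' @param results A [svr_deconvolve()] result over the paired samples.
#' @param observed Tibble sample_id, population, proportion.
#' @param calibration A [calibrate()] result.
#' @return A ggplot, faceted by population.
#' @export
plot_calibration <- function(results, observed, calibration) {
  df <- results |>
    dplyr::inner_join(observed, by = c("sample_id", "population"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_coefficient,
                                   y = .data$proportion)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(
      data = calibration,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "steelblue") +
    ggplot2::facet_wrap(~population, scales = "free") +
    ggplot2::labs(x = "SVR coefficient", y = "Observed proportion") +
    ggplot2::theme_minimal()
}
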
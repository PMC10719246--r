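#' Box plots of per-level relative variability
#'
#' Mirrors the usual presentation of baseline sensitivity results: one box
#' of per-jurisdiction CVs per level of each grid parameter.
#'
#' @param variability Output of [per_level_variability()] (optionally
#'   row-bound across parameters).
#' @return A ggplot object.
#' @export
plot_variability <- function(variability) {
  dat <- dplyr::filter(variability, !is.na(.data$cv_percent))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$cv_percent)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Relative variability (% CV)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of random-forest variable importance
#'
#' @param importance An `importance_result` from [variable_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  dat <- dplyr::mutate(importance,
                       parameter = stats::reorder(.data$parameter,
                                                  .data$importance_mean))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$importance_mean, y = .data$parameter)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      xmin = .data$importance_mean - .data$importance_se,
      xmax = .data$importance_mean + .data$importance_se), width = 0.25) +
    ggplot2::labs(x = "Permutation importance (mean ± SE)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot importance_result
#' @export
autoplot.importance_result <- function(object, ...) plot_importance(object)

#' Box plots of hindcast forecast errors by projection approach
#'
#' @param forecast_errors Output of [hindcast_grid()].
#' @return A ggplot object.
#' @export
plot_forecast_error <- function(forecast_errors) {
  dat <- dplyr::filter(forecast_errors, !is.na(.data$forecast_error))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$approach, y = .data$forecast_error)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "|predicted - actual| / actual") +
    ggplot2::theme_minimal()
}
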
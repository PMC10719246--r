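#' Tidy a fitted driver model
#'
#' One row per retained term with its coefficient on the Box-Cox-transformed
#' rate scale.
#'
#' @param x A `driver_model`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std_error`, `statistic`, `p_value`).
#' @method tidy driver_model
#' @export
tidy.driver_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' One-row summary of a fitted driver model
#'
#' @param x A `driver_model`.
#' @param ... Unused.
#' @return Tibble with scope, window, Box-Cox lambda and offset, fit size,
#'   counts of retained drivers and removed outliers, and R-squared.
#' @method glance driver_model
#' @export
glance.driver_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    scope = x$scope, dataset_variant = x$dataset_variant,
    start_year = x$start_year, ref_length = x$ref_length,
    boxcox_lambda = x$lambda, offset = x$offset,
    n_fit = x$n_fit,
    n_drivers_retained = length(x$drivers_retained),
    n_outliers_removed = length(x$outlier_ids),
    r_squared = sm$r.squared, sigma = sm$sigma
  )
}

#' Tidy a level comparison (Tukey HSD pairs)
#'
#' @param x A `level_comparison` from [compare_levels()].
#' @param ... Unused.
#' @return The Tukey pairwise tibble.
#' @method tidy level_comparison
#' @export
tidy.level_comparison <- function(x, ...) x$tukey

#' One-row ANOVA summary of a level comparison
#'
#' @param x A `level_comparison`.
#' @param ... Unused.
#' @return Tibble (`df_between`, `df_within`, `statistic`, `p_value`, `n`).
#' @method glance level_comparison
#' @export
glance.level_comparison <- function(x, ...) {
  dplyr::mutate(x$anova, n = x$n)
}
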
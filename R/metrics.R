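#' Coefficient of variation in percent
#'
#' Relative variability of a set of baselines: 100 x sample standard
#' deviation (n-1 denominator) / mean. Undefined (returned as `NA`) when the
#' mean is not positive.
#'
#' @param values Numeric vector, length >= 2.
#' @return CV in percent, or `NA_real_` if undefined.
#' @export
#' @examples
#' relative_variability(c(1, 2, 3))  # 50
relative_variability <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Overall per-jurisdiction relative variability of baselines
#'
#' @param baselines Baseline record tibble from [run_grid()].
#' @return Tibble (`jurisdiction_id`, `cv_percent`, `n_methods`) over valid
#'   records.
#' @export
overall_variability <- function(baselines) {
  baselines |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$jurisdiction_id) |>
    dplyr::summarise(cv_percent = relative_variability(.data$baseline_tco2e),
                     n_methods = dplyr::n(), .groups = "drop")
}

#' Per-level relative variability for one grid parameter
#'
#' For each jurisdiction and each level of `parameter` (e.g. each projection
#' approach), the CV of all valid baselines that use that level, with every
#' other parameter free. Levels with fewer than two records per jurisdiction
#' yield `NA`.
#'
#' @param baselines Baseline record tibble.
#' @param parameter One of the grid parameter column names (`"approach"`,
#'   `"defor_variant"`, `"ref_length"`, `"start_year"`,
#'   `"carbon_mask_variant"`, `"agb_source"`, `"bgb_source"`,
#'   `"soc_source"`).
#' @return Tibble (`jurisdiction_id`, `parameter`, `level`, `cv_percent`,
#'   `n_methods`).
#' @export
per_level_variability <- function(baselines, parameter) {
  if (!parameter %in% names(baselines)) abort_config("unknown grid parameter")
  baselines |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$jurisdiction_id,
                    level = as.character(.data[[parameter]])) |>
    dplyr::summarise(cv_percent = relative_variability(.data$baseline_tco2e),
                     n_methods = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(parameter = parameter, .after = "jurisdiction_id")
}

#' Hindcast one projection method against the ensuing window
#'
#' Fits the projection on the reference window and scores it against the
#' observed mean rate over the following window of equal duration:
#' forecast error = |predicted - actual| / actual. Records with zero actual
#' rate are excluded (reason-coded), not assigned infinite error.
#'
#' @param data A `defor_sim`.
#' @param jurisdiction_id Jurisdiction to score.
#' @param approach One of the seven projection approaches.
#' @param variant Forest-dataset variant.
#' @param start_year,ref_length Reference window; the series must also
#'   contain `start_year + ref_length .. start_year + 2 * ref_length - 1`.
#' @param config A [grid_config()] supplying ensemble settings.
#' @param seed Integer seed (ensemble approaches).
#' @return One-row tibble (`jurisdiction_id`, `approach`, `variant`,
#'   `start_year`, `ref_length`, `predicted_rate`, `actual_rate`,
#'   `forecast_error`, `reason`).
#' @export
hindcast_evaluate <- function(data, jurisdiction_id, approach, variant,
                              start_year, ref_length,
                              config = grid_config(), seed = 1L) {
  res <- hindcast_cells(
    data,
    tibble::tibble(approach = approach, defor_variant = variant,
                   ref_length = as.integer(ref_length),
                   start_year = as.integer(start_year)),
    config, seed)
  dplyr::filter(res, .data$jurisdiction_id == !!jurisdiction_id)
}

#' Hindcast every grid cell with an available ensuing window
#'
#' @param data A `defor_sim`.
#' @param config A [grid_config()].
#' @param seed Integer seed.
#' @return Forecast-error tibble across jurisdictions and cells.
#' @export
hindcast_grid <- function(data, config, seed = 1L) {
  cells <- projection_cells(config, data$config$variants) |>
    tidyr::expand_grid(approach = config$approaches)
  spans <- data$config$variants
  cells <- dplyr::left_join(cells, spans[, c("variant", "last_year")],
                            by = c(defor_variant = "variant")) |>
    dplyr::filter(.data$start_year + 2L * .data$ref_length - 1L <= .data$last_year) |>
    dplyr::select(-"last_year")
  if (!nrow(cells)) return(tibble::tibble())
  hindcast_cells(data, cells, config, seed)
}

hindcast_cells <- function(data, cells, config, seed) {
  actuals <- function(variant, fstart, flen) {
    data$panels |>
      dplyr::filter(.data$variant == !!variant, .data$year >= fstart,
                    .data$year <= fstart + flen - 1L, !is.na(.data$defor_km2)) |>
      dplyr::group_by(.data$jurisdiction_id) |>
      dplyr::summarise(actual_rate = mean(.data$defor_km2),
                       n_years = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n_years == flen) |>
      dplyr::select(-"n_years")
  }
  purrr::pmap_dfr(
    cells[, c("approach", "defor_variant", "ref_length", "start_year")],
    function(approach, defor_variant, ref_length, start_year) {
      pred <- project_approach_cell(data, approach, defor_variant, start_year,
                                    ref_length,
                                    ensemble_reps = config$ensemble_reps,
                                    size_range = config$ensemble_size_range,
                                    seed = seed) |>
        screen_nonnegative()
      act <- actuals(defor_variant, start_year + ref_length, ref_length)
      dplyr::inner_join(pred, act, by = "jurisdiction_id") |>
        dplyr::transmute(
          .data$jurisdiction_id, approach = approach,
          variant = defor_variant, start_year = start_year,
          ref_length = ref_length,
          predicted_rate = .data$point_rate, .data$actual_rate,
          forecast_error = dplyr::if_else(
            .data$valid & .data$actual_rate > 0,
            abs(.data$predicted_rate - .data$actual_rate) / .data$actual_rate,
            NA_real_),
          reason = dplyr::case_when(
            !.data$valid ~ "invalid projection",
            .data$actual_rate == 0 ~ "zero actual rate",
            TRUE ~ NA_character_)
        )
    })
}

#' Per-jurisdiction uncertainty summaries and threshold exceedance
#'
#' For each jurisdiction and uncertainty component -- the propagated
#' baseline uncertainty, the projection-model uncertainty, the combined
#' carbon uncertainty, and the AGB-carbon and BGB-carbon pool uncertainties
#' -- reports the median relative uncertainty (in percent) across valid
#' method combinations and the fraction of methods exceeding the threshold.
#' Historical-average combinations carry no model uncertainty and are
#' excluded from the baseline and projection pools.
#'
#' @param baselines Baseline record tibble.
#' @param threshold Exceedance threshold in percent (default 15, the level
#'   above which crediting standards typically require a discount).
#' @return Tibble (`jurisdiction_id`, `component`,
#'   `median_rel_uncertainty_pct`, `fraction_exceeding`, `threshold_pct`,
#'   `n_methods`).
#' @export
uncertainty_summaries <- function(baselines, threshold = 15) {
  comp_cols <- c(baseline = "propagated_rel_u", projection = "rate_rel_u",
                 carbon = "carbon_rel_u", agbc = "agb_rel_u", bgbc = "bgb_rel_u")
  purrr::imap_dfr(comp_cols, function(col, comp) {
    baselines |>
      dplyr::filter(.data$valid, !is.na(.data[[col]])) |>
      dplyr::group_by(.data$jurisdiction_id) |>
      dplyr::summarise(
        component = comp,
        median_rel_uncertainty_pct = stats::median(100 * .data[[col]]),
        fraction_exceeding = mean(100 * .data[[col]] > threshold),
        threshold_pct = threshold,
        n_methods = dplyr::n(), .groups = "drop")
  })
}

#' Compare levels of a grid parameter by one-way ANOVA and Tukey HSD
#'
#' Treats per-jurisdiction level statistics (CVs or forecast errors) as
#' observations and tests whether levels differ, reporting the ANOVA F test
#' and Tukey honest-significant-difference adjusted p-values for all level
#' pairs. Levels with fewer than two observations are dropped with a
#' warning.
#'
#' @param level_stats Tibble with a `level` column and a numeric value
#'   column.
#' @param value_col Name of the value column (default `"cv_percent"`).
#' @return An object of class `level_comparison` with `anova` and `tukey`
#'   tibbles; see [tidy.level_comparison()].
#' @export
compare_levels <- function(level_stats, value_col = "cv_percent") {
  df <- tibble::tibble(
    value = level_stats[[value_col]],
    level = as.character(level_stats$level)
  )
  df <- df[!is.na(df$value), ]
  counts <- table(df$level)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping levels with fewer than 2 values: ",
            paste(small, collapse = ", "))
    df <- df[!df$level %in% small, ]
  }
  if (length(unique(df$level)) < 2L) abort_data("need at least two levels to compare")
  df$level <- factor(df$level)
  fit <- stats::aov(value ~ level, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$level
  structure(list(
    anova = tibble::tibble(
      df_between = an$Df[1], df_within = an$Df[2],
      statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
    tukey = tibble::tibble(
      contrast = rownames(tk), estimate = tk[, "diff"],
      conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
      adj_p_value = tk[, "p adj"]),
    value_col = value_col,
    n = nrow(df)
  ), class = "level_comparison")
}

#' @export
print.level_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.3g, p = %.3g\n",
              x$value_col, x$anova$df_between, x$anova$df_within,
              x$anova$statistic, x$anova$p_value))
  print(x$tukey, n = Inf)
  invisible(x)
}

#' Correlation between log forest area and baseline variability
#'
#' Pearson correlation of log-transformed forest area against the overall
#' per-jurisdiction CV, with its p-value.
#'
#' @param data Tibble pairing jurisdictions' forest areas and CVs.
#' @param area_col,cv_col Column names (defaults `"forest_km2"`,
#'   `"cv_percent"`).
#' @return One-row tibble (`pearson_r`, `p_value`, `n`).
#' @export
area_variability_correlation <- function(data, area_col = "forest_km2",
                                         cv_col = "cv_percent") {
  x <- data[[area_col]]
  y <- data[[cv_col]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_data("need at least 3 paired observations")
  if (any(x <= 0)) abort_data("forest areas must be positive for the log transform")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort_data("zero variance: correlation undefined")
  ct <- stats::cor.test(log(x), y, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
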
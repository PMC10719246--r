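#' @importFrom rlang .data
NULL

projection_result <- function(approach, point, lower = NA_real_, upper = NA_real_,
                              valid = TRUE) {
  rel <- if (!is.na(point) && !is.na(lower) && !is.na(upper) && point > 0) {
    (upper - lower) / (2 * point)
  } else {
    NA_real_
  }
  tibble::tibble(
    approach = approach,
    point_rate = point, pi_lower = lower, pi_upper = upper,
    rel_uncertainty = rel,
    valid = valid && is.finite(point)
  )
}

check_window <- function(years, start_year, ref_length) {
  want <- seq.int(start_year, start_year + ref_length - 1L)
  if (!all(want %in% years)) {
    abort_range(sprintf("reference window %d..%d extends outside the series",
                        start_year, start_year + ref_length - 1L))
  }
  want
}

#' Historical-average projection
#'
#' Continues the arithmetic mean annual deforestation rate of the reference
#' window into the future. No prediction interval is attached: model-based
#' uncertainties are derived from the time-function and driver models only,
#' and historical-average combinations are excluded from uncertainty
#' summaries.
#'
#' @param data Tibble with columns `year` and `defor_km2` for one
#'   jurisdiction and dataset variant.
#' @param start_year First year of the reference window.
#' @param ref_length Window length in years.
#' @return One-row projection tibble (`approach`, `point_rate`, `pi_lower`,
#'   `pi_upper`, `rel_uncertainty`, `valid`).
#' @export
#' @examples
#' d <- tibble::tibble(year = 2001:2003, defor_km2 = c(10, 12, 14))
#' project_historical_average(d, 2001, 3)$point_rate  # 12
project_historical_average <- function(data, start_year, ref_length) {
  yrs <- check_window(data$year[!is.na(data$defor_km2)], start_year, ref_length)
  projection_result("hist", mean(data$defor_km2[match(yrs, data$year)]))
}

#' Time-function projection (linear or quadratic trend)
#'
#' Fits a least-squares polynomial of the annual rate on year over the
#' reference window and projects it over the following window of equal
#' length. The point projection is the mean of the fitted curve over that
#' future window; the 90% prediction interval is the interval for that mean
#' of future observations (trend-coefficient variance plus residual variance
#' shrunk by the horizon length).
#'
#' @inheritParams project_historical_average
#' @param degree Polynomial degree, 1 (`linear`) or 2 (`poly2`).
#' @return One-row projection tibble.
#' @export
project_time_function <- function(data, start_year, ref_length, degree = 1) {
  if (!degree %in% c(1, 2)) abort_config("degree must be 1 or 2")
  if (ref_length < degree + 2) abort_range("window too short for the requested degree")
  yrs <- check_window(data$year[!is.na(data$defor_km2)], start_year, ref_length)
  y <- data$defor_km2[match(yrs, data$year)]
  est <- time_function_core(yrs - start_year, y, ref_length, degree)
  projection_result(if (degree == 1) "linear" else "poly2",
                    est[1], est[2], est[3])
}

# least-squares polynomial trend with the 90% interval for the mean of the
# next `horizon` observations; returns c(point, lower, upper)
time_function_core <- function(t0, y, horizon, degree) {
  if (length(unique(t0)) < degree + 1) abort_fit("degenerate design: years not distinct")
  X <- cbind(1, t0, if (degree == 2) t0^2)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) abort_fit("singular time-function design")
  beta <- qr.coef(qr_x, y)
  tf <- seq.int(horizon, 2L * horizon - 1L)
  Xf <- cbind(1, tf, if (degree == 2) tf^2)
  point <- mean(drop(Xf %*% beta))
  dfres <- length(y) - ncol(X)
  if (dfres >= 1) {
    s2 <- sum(qr.resid(qr_x, y)^2) / dfres
    a <- colMeans(Xf)
    var_mean <- drop(crossprod(a, solve(crossprod(X), a))) * s2 + s2 / length(tf)
    half <- stats::qt(0.95, dfres) * sqrt(max(var_mean, 0))
    c(point, point - half, point + half)
  } else {
    c(point, NA_real_, NA_real_)
  }
}

# ---- Box-Cox helpers ------------------------------------------------------

bc_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

# inverse is monotone increasing on its domain; values outside the image of
# the transform map to the boundary (0 for positive lambda, +Inf for
# negative, where the transform saturates); infinite predictions are
# flagged invalid downstream
bc_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-8) return(exp(z))
  base <- lambda * z + 1
  if (lambda > 0) {
    pmax(base, 0)^(1 / lambda)
  } else {
    ifelse(base <= 0, Inf, base^(1 / lambda))
  }
}

#' Per-jurisdiction window means of the driver covariates
#'
#' @param drivers Driver tibble (`jurisdiction_id`, `year`, twelve columns).
#' @param start_year,ref_length Reference window.
#' @return Tibble with one row per jurisdiction of window-mean drivers.
#' @export
driver_window_means <- function(drivers, start_year, ref_length) {
  drivers |>
    dplyr::filter(.data$year >= start_year,
                  .data$year <= start_year + ref_length - 1L) |>
    dplyr::group_by(.data$jurisdiction_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(driver_names()), mean),
                     .groups = "drop")
}

#' Fit a driver-based deforestation model
#'
#' Regresses the per-jurisdiction mean annual deforestation rate over a
#' reference window on (window-mean) driver covariates, either globally or
#' within one region. The response is Box-Cox transformed with the power
#' chosen by maximum profile likelihood (a half-minimum-positive offset is
#' added first if zero rates are present); observations with absolute
#' studentized residual above 3 in a preliminary full fit are removed in one
#' pass; bidirectional stepwise elimination by AIC then prunes the supplied
#' driver subset.
#'
#' @param data A `defor_sim`-like list with `panels`, `drivers` and
#'   `jurisdictions` tibbles.
#' @param scope `"global"` or one of [region_labels()].
#' @param dataset_variant Forest-dataset variant supplying the response.
#' @param start_year,ref_length Reference window.
#' @param drivers Character vector of candidate driver names (default all 12).
#' @return An object of class `driver_model`.
#' @export
fit_driver_model <- function(data, scope, dataset_variant, start_year, ref_length,
                             drivers = driver_names()) {
  df <- assemble_driver_data(data, scope, dataset_variant, start_year, ref_length)
  fit_driver_model_df(df, drivers, scope, dataset_variant, start_year, ref_length)
}

# per-jurisdiction window-mean response and drivers for one scope/variant/window
assemble_driver_data <- function(data, scope, dataset_variant, start_year, ref_length) {
  jur <- data$jurisdictions
  if (scope != "global") {
    jur <- dplyr::filter(jur, .data$region == scope)
  }
  resp <- data$panels |>
    dplyr::filter(.data$variant == dataset_variant,
                  .data$jurisdiction_id %in% jur$jurisdiction_id,
                  .data$year >= start_year,
                  .data$year <= start_year + ref_length - 1L,
                  !is.na(.data$defor_km2)) |>
    dplyr::group_by(.data$jurisdiction_id) |>
    dplyr::summarise(rate = mean(.data$defor_km2), n_years = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_years == ref_length, .data$rate >= 0)
  xmeans <- driver_window_means(data$drivers, start_year, ref_length)
  dplyr::inner_join(resp, xmeans, by = "jurisdiction_id")
}

fit_driver_model_df <- function(df, drivers, scope, dataset_variant,
                                start_year, ref_length) {
  if (!length(drivers) || !all(drivers %in% driver_names())) {
    abort_config("drivers must be a non-empty subset of driver_names()")
  }
  df <- df[stats::complete.cases(df[, c("rate", drivers)]), ]
  if (sum(df$rate > 0) < length(drivers) + 5L) {
    abort_fit(sprintf(
      "need at least %d jurisdictions with positive mean rate in scope '%s'; have %d",
      length(drivers) + 5L, scope, sum(df$rate > 0)))
  }

  offset <- if (any(df$rate <= 0)) min(df$rate[df$rate > 0]) / 2 else 0
  y <- df$rate + offset
  fml <- stats::reformulate(drivers, response = "y_bc")
  fit_df <- df[, drivers]

  if (stats::sd(y) < 1e-10 * max(mean(y), 1e-300)) {
    lambda <- 1  # degenerate constant response: transform is irrelevant
  } else {
    bc_df <- cbind(data.frame(y_raw = y), fit_df)
    prof <- MASS::boxcox(stats::reformulate(drivers, response = "y_raw"),
                         data = bc_df, lambda = seq(-2, 2, 0.01), plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }

  fit_df$y_bc <- bc_transform(y, lambda)
  full <- stats::lm(fml, data = fit_df)
  rs <- stats::rstudent(full)
  out_idx <- which(!is.na(rs) & abs(rs) > 3)
  outlier_ids <- df$jurisdiction_id[out_idx]
  if (length(out_idx)) {
    fit_df <- fit_df[-out_idx, , drop = FALSE]
    full <- stats::lm(fml, data = fit_df)
  }
  reduced <- if (full$df.residual > 0 && stats::sd(fit_df$y_bc) > 0) {
    stats::step(full, scope = list(lower = ~1, upper = fml),
                direction = "both", trace = 0)
  } else {
    full
  }

  structure(list(
    fit = reduced, lambda = lambda, offset = offset,
    scope = scope, dataset_variant = dataset_variant,
    start_year = start_year, ref_length = ref_length,
    drivers_supplied = drivers,
    drivers_retained = intersect(drivers, attr(stats::terms(reduced), "term.labels")),
    outlier_ids = outlier_ids,
    n_fit = nrow(fit_df)
  ), class = "driver_model")
}

#' @export
print.driver_model <- function(x, ...) {
  cat(sprintf("<driver_model> scope=%s variant=%s window=%d+%dyr lambda=%.2f\n",
              x$scope, x$dataset_variant, x$start_year, x$ref_length, x$lambda))
  cat("retained drivers:", if (length(x$drivers_retained)) paste(x$drivers_retained, collapse = ", ") else "(intercept only)", "\n")
  if (length(x$outlier_ids)) cat("outliers removed:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Predict deforestation rates from a fitted driver model
#'
#' Computes the point prediction and 90% prediction interval on the
#' transformed scale, then back-transforms both monotonically to the rate
#' scale (so interval ordering is preserved), subtracts the Box-Cox offset
#' and floors at zero.
#'
#' @param model A `driver_model`.
#' @param new_drivers Tibble with `jurisdiction_id` and window-mean driver
#'   columns (see [driver_window_means()]).
#' @return Projection tibble with one row per jurisdiction.
#' @export
predict_driver_model <- function(model, new_drivers) {
  need <- model$drivers_retained
  if (!all(need %in% names(new_drivers)) ||
      anyNA(new_drivers[, need])) {
    abort_data("missing driver values in new_drivers")
  }
  approach <- if (model$scope == "global") "global" else "regional"
  pr <- stats::predict(model$fit, newdata = new_drivers,
                       interval = "prediction", level = 0.90)
  back <- function(z) pmax(bc_inverse(z, model$lambda) - model$offset, 0)
  pt <- unname(back(pr[, "fit"]))
  lo <- unname(back(pr[, "lwr"]))
  hi <- unname(back(pr[, "upr"]))
  tibble::tibble(
    jurisdiction_id = new_drivers$jurisdiction_id,
    approach = approach,
    point_rate = pt, pi_lower = lo, pi_upper = hi,
    rel_uncertainty = dplyr::if_else(pt > 0, (hi - lo) / (2 * pt), NA_real_),
    valid = is.finite(pt)
  )
}

#' Multi-model ensemble projection over random driver subsets
#'
#' Fits `reps` driver models, each on a random driver subset whose size is
#' drawn uniformly from `size_range`, and averages their back-transformed
#' point predictions per jurisdiction. The 90% interval is taken as the
#' 5th--95th percentile of the member predictions. Members whose fit fails
#' (for example a singular or under-determined design) are dropped and
#' counted; more than 50% failures aborts.
#'
#' @inheritParams fit_driver_model
#' @param reps Number of ensemble members.
#' @param size_range Inclusive range of driver-subset sizes.
#' @param seed Integer seed for member subset draws.
#' @param new_drivers Optional window-mean driver tibble to predict for;
#'   defaults to every jurisdiction in scope.
#' @return Projection tibble with one row per jurisdiction plus `n_members`
#'   and `n_failed` columns.
#' @export
ensemble_predict <- function(data, scope, dataset_variant, start_year, ref_length,
                             reps = 300, size_range = c(3, 11), seed = 1L,
                             new_drivers = NULL) {
  if (is.null(new_drivers)) {
    ids <- data$jurisdictions
    if (scope != "global") ids <- dplyr::filter(ids, .data$region == scope)
    new_drivers <- driver_window_means(data$drivers, start_year, ref_length) |>
      dplyr::filter(.data$jurisdiction_id %in% ids$jurisdiction_id)
  }
  sizes <- seq.int(max(1L, size_range[1]), min(size_range[2], length(driver_names())))
  fit_df <- assemble_driver_data(data, scope, dataset_variant, start_year, ref_length)
  preds <- matrix(NA_real_, nrow = nrow(new_drivers), ncol = reps)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    subset_r <- with_stream_seed(stream_seed(seed, "ensemble_member", r), {
      k <- if (length(sizes) == 1L) sizes else sizes[sample_int(length(sizes), 1L)]
      driver_names()[sample_int(length(driver_names()), k)]
    })
    member <- tryCatch(
      fit_driver_model_df(fit_df, subset_r, scope, dataset_variant,
                          start_year, ref_length),
      error = function(e) NULL)
    if (is.null(member)) {
      n_failed <- n_failed + 1L
      next
    }
    pr <- tryCatch(predict_driver_model(member, new_drivers), error = function(e) NULL)
    if (is.null(pr)) {
      n_failed <- n_failed + 1L
      next
    }
    preds[, r] <- pr$point_rate
  }
  if (n_failed > reps / 2) {
    abort_fit(sprintf("ensemble failure: %d of %d members failed", n_failed, reps))
  }
  approach <- if (scope == "global") "global_s" else "regional_s"
  ok <- !is.na(preds[1, ])
  m <- preds[, ok, drop = FALSE]
  pt <- rowMeans(m)
  q <- t(apply(m, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE))
  tibble::tibble(
    jurisdiction_id = new_drivers$jurisdiction_id,
    approach = approach,
    point_rate = pt, pi_lower = q[, 1], pi_upper = q[, 2],
    rel_uncertainty = dplyr::if_else(pt > 0, (q[, 2] - q[, 1]) / (2 * pt), NA_real_),
    valid = is.finite(pt),
    n_members = sum(ok), n_failed = n_failed
  )
}

#' Screen out negative projected deforestation rates
#'
#' Methods that project negative deforestation would be rejected in actual
#' baseline submissions, so such results are flagged invalid (not clamped to
#' zero) and excluded from all downstream statistics. For valid results the
#' lower interval bound is floored at zero, since rates cannot be negative.
#'
#' @param results Projection tibble (any number of rows).
#' @return The tibble with `valid` and `pi_lower` updated.
#' @export
screen_nonnegative <- function(results) {
  results |>
    dplyr::mutate(
      valid = .data$valid & !is.na(.data$point_rate) & .data$point_rate >= 0,
      pi_lower = dplyr::if_else(.data$valid & !is.na(.data$pi_lower),
                                pmax(.data$pi_lower, 0), .data$pi_lower)
    )
}
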
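#' Random-forest variable importance of the grid parameters
#'
#' Ranks the method-grid parameters by how strongly they influence the
#' computed baselines. Bootstraps `n_models` random-forest fits (each on a
#' random row subsample of the valid records, `n_trees` trees, permutation
#' importance on out-of-bag rows) and reports the mean and standard error of
#' each parameter's importance across models.
#'
#' @param baselines Baseline record tibble (or any tibble with the parameter
#'   columns and a response column).
#' @param response Response column name (default `"baseline_tco2e"`).
#' @param parameters Predictor columns; defaults to the grid parameters
#'   without `start_year` (switch `include_start_year` on to add it).
#' @param include_start_year Add `start_year` to the predictors.
#' @param n_models Number of bootstrapped forest fits.
#' @param n_trees Trees per forest.
#' @param sample_rows Rows subsampled (without replacement) per model;
#'   shrunk to the available rows when fewer exist.
#' @param seed Integer seed.
#' @return Tibble of class `importance_result` (`parameter`,
#'   `importance_mean`, `importance_se`, `n_models`, `rank`).
#' @export
variable_importance <- function(baselines,
                                response = "baseline_tco2e",
                                parameters = c("approach", "defor_variant",
                                               "ref_length",
                                               "carbon_mask_variant",
                                               "agb_source", "bgb_source",
                                               "soc_source"),
                                include_start_year = FALSE,
                                n_models = 20, n_trees = 50,
                                sample_rows = 50000, seed = 1L) {
  if (include_start_year) parameters <- union(parameters, "start_year")
  df <- baselines
  if ("valid" %in% names(df)) df <- dplyr::filter(df, .data$valid)
  df <- df[!is.na(df[[response]]), c(response, parameters)]
  keep <- parameters[vapply(parameters, function(p) {
    length(unique(df[[p]])) > 1L
  }, logical(1))]
  dropped <- setdiff(parameters, keep)
  if (length(dropped)) {
    warning("dropping single-level predictors: ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) abort_data("no predictor varies")
  for (p in keep) df[[p]] <- factor(df[[p]])
  n_avail <- nrow(df)
  m <- min(sample_rows, n_avail)
  if (m < sample_rows) {
    message(sprintf("sample_rows shrunk from %d to the %d available rows",
                    sample_rows, n_avail))
  }
  fml <- stats::reformulate(keep, response = response)
  imp <- matrix(NA_real_, nrow = n_models, ncol = length(keep),
                dimnames = list(NULL, keep))
  for (b in seq_len(n_models)) {
    rows <- with_stream_seed(stream_seed(seed, "rf_rows", b),
                             sample_int(n_avail, m))
    fit <- ranger::ranger(
      fml, data = df[rows, ], num.trees = n_trees,
      importance = "permutation",
      respect.unordered.factors = "order",
      num.threads = 1,
      seed = stream_seed(seed, "rf_fit", b))
    imp[b, names(fit$variable.importance)] <- fit$variable.importance
  }
  out <- tibble::tibble(
    parameter = keep,
    importance_mean = colMeans(imp),
    importance_se = apply(imp, 2, stats::sd) / sqrt(n_models),
    n_models = n_models
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance_mean)) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (max(abs(out$importance_mean)) < .Machine$double.eps^0.5) {
    attr(out, "constant_response") <- TRUE
  }
  class(out) <- c("importance_result", class(out))
  out
}
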
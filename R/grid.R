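#' Enumerate all permitted method combinations
#'
#' Builds the Cartesian product of projection approach, deforestation
#' dataset variant, reference length, admissible start year, carbon forest
#' mask and AGB/BGB/SOC sources, keeping only combinations whose reference
#' window fits entirely inside the variant's span. The order is
#' deterministic and each combination carries a stable id.
#'
#' @param config A [grid_config()].
#' @param variants Variant span table (columns `variant`, `first_year`,
#'   `last_year`), e.g. `generator_config()$variants`.
#' @return Tibble of combinations with a `combination_id` column.
#' @export
#' @examples
#' cfg <- grid_config(approaches = c("hist", "linear"), ref_lengths = 5,
#'                    n_start_years = 1, agb_sources = "spawn_agb",
#'                    bgb_sources = "ipcc_bgb", soc_sources = "esdac_soc",
#'                    defor_variants = "modis", carbon_mask_variants = "modis")
#' nrow(enumerate_combinations(cfg, default_variants()))  # 2
enumerate_combinations <- function(config, variants) {
  proj <- projection_cells(config, variants) |>
    tidyr::expand_grid(approach = config$approaches) |>
    dplyr::relocate("approach")
  carbon <- tidyr::expand_grid(
    carbon_mask_variant = config$carbon_mask_variants,
    agb_source = config$agb_sources,
    bgb_source = config$bgb_sources,
    soc_source = config$soc_sources
  )
  out <- tidyr::expand_grid(proj, carbon)
  if (!nrow(out)) abort_config("empty method grid")
  out |>
    dplyr::arrange(.data$approach, .data$defor_variant, .data$ref_length,
                   .data$start_year, .data$carbon_mask_variant,
                   .data$agb_source, .data$bgb_source, .data$soc_source) |>
    dplyr::mutate(combination_id = paste(
      .data$approach, .data$defor_variant, .data$ref_length, .data$start_year,
      .data$carbon_mask_variant, .data$agb_source, .data$bgb_source,
      .data$soc_source, sep = "|"))
}

# (variant, ref_length, start_year) cells whose window fits the span; the
# first rate year of a variant is the year after its first mapped year
projection_cells <- function(config, variants) {
  v <- variants[variants$variant %in% config$defor_variants, ]
  purrr::pmap_dfr(
    list(v$variant, v$first_year, v$last_year),
    function(variant, first, last) {
      purrr::map_dfr(config$ref_lengths, function(L) {
        starts <- seq.int(first + 1L, last - L + 1L)
        if (!is.null(config$n_start_years) && length(starts) > config$n_start_years) {
          idx <- unique(round(seq(1, length(starts),
                                  length.out = config$n_start_years)))
          starts <- starts[idx]
        }
        tibble::tibble(defor_variant = variant, ref_length = L, start_year = starts)
      })
    })
}

#' Propagate rate and carbon uncertainties in quadrature
#'
#' @param rate_rel_u Relative uncertainty of the projected rate (`NA` for
#'   historical-average combinations, which carry no model uncertainty).
#' @param carbon_rel_u Relative uncertainty of the carbon density.
#' @return `sqrt(rate_rel_u^2 + carbon_rel_u^2)`, `NA` where the rate term
#'   is absent.
#' @export
#' @examples
#' propagate_uncertainty(0.3, 0.4)  # 0.5
propagate_uncertainty <- function(rate_rel_u, carbon_rel_u) {
  if (any(rate_rel_u < 0, na.rm = TRUE) || any(carbon_rel_u < 0, na.rm = TRUE)) {
    abort_data("relative uncertainties must be non-negative")
  }
  sqrt(rate_rel_u^2 + carbon_rel_u^2)
}

#' Combine projections and carbon estimates into baseline records
#'
#' The deforestation emission baseline of a method combination is the
#' product of its projected deforestation rate (km2/yr) and its average
#' forest carbon density (tCO2e/km2). Invalid (negative-rate) projections
#' yield records flagged `valid = FALSE` that are retained for audit but
#' excluded from statistics.
#'
#' @param projections Projection tibble with `jurisdiction_id`, `approach`,
#'   `defor_variant`, `ref_length`, `start_year` and result columns.
#' @param carbon_estimates Output of [estimate_carbon()].
#' @return Baseline record tibble (one row per projection x carbon
#'   combination per jurisdiction).
#' @export
compute_baseline <- function(projections, carbon_estimates) {
  out <- dplyr::inner_join(
    projections,
    dplyr::rename(carbon_estimates, carbon_rel_u = "rel_uncertainty"),
    by = "jurisdiction_id", relationship = "many-to-many")
  out |>
    dplyr::mutate(
      baseline_tco2e = dplyr::if_else(.data$valid,
                                      .data$point_rate * .data$co2e_t_per_km2,
                                      NA_real_),
      rate_rel_u = .data$rel_uncertainty,
      propagated_rel_u = propagate_uncertainty(.data$rate_rel_u, .data$carbon_rel_u),
      combination_id = paste(.data$approach, .data$defor_variant,
                             .data$ref_length, .data$start_year,
                             .data$carbon_mask_variant, .data$agb_source,
                             .data$bgb_source, .data$soc_source, sep = "|")
    ) |>
    dplyr::select("jurisdiction_id", "combination_id", "approach",
                  "defor_variant", "ref_length", "start_year",
                  "carbon_mask_variant", "agb_source", "bgb_source",
                  "soc_source", "point_rate", "pi_lower", "pi_upper",
                  "co2e_t_per_km2", "baseline_tco2e",
                  "rate_rel_u", "carbon_rel_u", "agb_rel_u", "bgb_rel_u",
                  "propagated_rel_u", "valid")
}

# one projection cell for all jurisdictions in `data`; failures yield
# valid = FALSE rows so downstream counting stays exhaustive
project_approach_cell <- function(data, approach, variant, start_year, ref_length,
                                  ensemble_reps = 50, size_range = c(3, 11),
                                  seed = 1L) {
  ids <- data$jurisdictions$jurisdiction_id
  invalid_rows <- function(which_ids) {
    tibble::tibble(jurisdiction_id = which_ids, approach = approach,
                   point_rate = NA_real_, pi_lower = NA_real_,
                   pi_upper = NA_real_, rel_uncertainty = NA_real_,
                   valid = FALSE)
  }
  # lean loop over pre-split series: fun(years, rates) -> c(point, lo, hi)
  per_series <- function(fun) {
    pan <- data$panels[data$panels$variant == variant & !is.na(data$panels$defor_km2), ]
    yr_split <- split(pan$year, pan$jurisdiction_id)
    y_split <- split(pan$defor_km2, pan$jurisdiction_id)
    out <- matrix(NA_real_, nrow = length(ids), ncol = 3)
    for (i in seq_along(ids)) {
      ser_y <- y_split[[ids[i]]]
      if (is.null(ser_y)) next
      est <- tryCatch(fun(yr_split[[ids[i]]], ser_y), error = function(e) NULL)
      if (!is.null(est)) out[i, ] <- est
    }
    pt <- out[, 1]
    tibble::tibble(
      jurisdiction_id = ids, approach = approach,
      point_rate = pt, pi_lower = out[, 2], pi_upper = out[, 3],
      rel_uncertainty = dplyr::if_else(!is.na(pt) & pt > 0,
                                       (out[, 3] - out[, 2]) / (2 * pt),
                                       NA_real_),
      valid = is.finite(pt)
    )
  }
  window_vals <- function(years, y) {
    idx <- match(seq.int(start_year, start_year + ref_length - 1L), years)
    if (anyNA(idx)) abort_range("window extends outside the series")
    y[idx]
  }
  scoped <- function(scopes, fit_predict) {
    purrr::map_dfr(scopes, function(sc) {
      in_scope <- if (sc == "global") ids else {
        data$jurisdictions$jurisdiction_id[data$jurisdictions$region == sc]
      }
      if (!length(in_scope)) return(invalid_rows(character(0)))
      res <- tryCatch(fit_predict(sc, in_scope), error = function(e) NULL)
      if (is.null(res)) invalid_rows(in_scope) else res
    })
  }
  out <- switch(
    approach,
    hist = per_series(function(years, y) c(mean(window_vals(years, y)), NA, NA)),
    linear = per_series(function(years, y) {
      time_function_core(0:(ref_length - 1L), window_vals(years, y), ref_length, 1)
    }),
    poly2 = per_series(function(years, y) {
      time_function_core(0:(ref_length - 1L), window_vals(years, y), ref_length, 2)
    }),
    global = scoped("global", function(sc, in_scope) {
      m <- fit_driver_model(data, sc, variant, start_year, ref_length)
      nd <- driver_window_means(data$drivers, start_year, ref_length) |>
        dplyr::filter(.data$jurisdiction_id %in% in_scope)
      predict_driver_model(m, nd)
    }),
    regional = scoped(unique(data$jurisdictions$region), function(sc, in_scope) {
      m <- fit_driver_model(data, sc, variant, start_year, ref_length)
      nd <- driver_window_means(data$drivers, start_year, ref_length) |>
        dplyr::filter(.data$jurisdiction_id %in% in_scope)
      predict_driver_model(m, nd)
    }),
    global_s = scoped("global", function(sc, in_scope) {
      ensemble_predict(data, sc, variant, start_year, ref_length,
                       reps = ensemble_reps, size_range = size_range,
                       seed = stream_seed(seed, "cell", approach, variant,
                                          start_year, ref_length, sc)) |>
        dplyr::select(-"n_members", -"n_failed")
    }),
    regional_s = scoped(unique(data$jurisdictions$region), function(sc, in_scope) {
      ensemble_predict(data, sc, variant, start_year, ref_length,
                       reps = ensemble_reps, size_range = size_range,
                       seed = stream_seed(seed, "cell", approach, variant,
                                          start_year, ref_length, sc)) |>
        dplyr::select(-"n_members", -"n_failed")
    }),
    abort_config(sprintf("unknown approach '%s'", approach))
  )
  # every jurisdiction gets exactly one row per cell
  missing <- setdiff(ids, out$jurisdiction_id)
  if (length(missing)) out <- dplyr::bind_rows(out, invalid_rows(missing))
  dplyr::mutate(out, defor_variant = variant, ref_length = ref_length,
                start_year = start_year)
}

#' Compute projections for every cell of the method grid
#'
#' Driver models are fitted once per (approach, scope, variant, window) cell
#' and their predictions reused across all jurisdictions; per-jurisdiction
#' approaches (historical average and time functions) are fitted per series.
#' Results are passed through [screen_nonnegative()].
#'
#' @param data A (screened) `defor_sim`.
#' @param config A [grid_config()].
#' @param seed Integer seed for the ensemble member streams.
#' @return Projection tibble across all jurisdictions and cells.
#' @export
run_projections <- function(data, config, seed = 1L) {
  cells <- projection_cells(config, data$config$variants) |>
    tidyr::expand_grid(approach = config$approaches)
  purrr::pmap_dfr(
    cells[, c("approach", "defor_variant", "ref_length", "start_year")],
    function(approach, defor_variant, ref_length, start_year) {
      project_approach_cell(data, approach, defor_variant, start_year,
                            ref_length,
                            ensemble_reps = config$ensemble_reps,
                            size_range = config$ensemble_size_range,
                            seed = seed)
    }) |>
    screen_nonnegative()
}

#' Run the full baseline grid
#'
#' Computes one baseline record per jurisdiction x method combination:
#' projections for every grid cell (with driver-model fits cached per cell),
#' carbon estimates for every carbon combination, and their product with
#' quadrature-propagated uncertainty. Jurisdictions can be processed in
#' chunks to bound memory.
#'
#' @param data A (screened) `defor_sim`.
#' @param carbon_layers Output of [generate_carbon_layers()] for `data`.
#' @param config A [grid_config()].
#' @param seed Integer seed (ensemble streams).
#' @param chunk_size Number of jurisdictions per processing chunk.
#' @return Baseline record tibble.
#' @export
run_grid <- function(data, carbon_layers, config, seed = 1L, chunk_size = Inf) {
  projections <- run_projections(data, config, seed = seed)
  carbon_grid <- tidyr::expand_grid(
    carbon_mask_variant = config$carbon_mask_variants,
    agb_source = config$agb_sources,
    bgb_source = config$bgb_sources,
    soc_source = config$soc_sources
  )
  carbon_est <- estimate_carbon(carbon_layers, carbon_grid)
  ids <- unique(data$jurisdictions$jurisdiction_id)
  chunks <- split(ids, ceiling(seq_along(ids) / min(chunk_size, length(ids))))
  purrr::map_dfr(chunks, function(chunk) {
    compute_baseline(
      dplyr::filter(projections, .data$jurisdiction_id %in% chunk),
      dplyr::filter(carbon_est, .data$jurisdiction_id %in% chunk))
  })
}
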
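#' Derive belowground from aboveground biomass via a root:shoot ratio
#'
#' @param agb_biomass Aboveground biomass density (Mg/ha), non-negative.
#' @param ratio Root:shoot ratio, positive.
#' @return Belowground biomass density in the same units.
#' @export
#' @examples
#' bgb_from_ratio(200, 0.25)  # 50
bgb_from_ratio <- function(agb_biomass, ratio) {
  if (any(ratio <= 0)) abort_config("root:shoot ratio must be > 0")
  if (any(agb_biomass < 0)) abort_data("aboveground biomass must be >= 0")
  agb_biomass * ratio
}

#' Relative uncertainty of a carbon source
#'
#' Returns the provider-supplied relative uncertainty when one is configured
#' and the 33% default otherwise.
#'
#' @param configured Provider relative uncertainty, or `NA` if none.
#' @return Positive relative uncertainty (dimensionless).
#' @export
default_uncertainty <- function(configured = NA_real_) {
  if (length(configured) != 1L) abort_config("one source at a time")
  if (is.na(configured)) return(0.33)
  if (configured <= 0) abort_config("configured uncertainty must be positive")
  configured
}

#' Combine pool uncertainties in quadrature
#'
#' The relative uncertainty of a sum of independent components is the root
#' sum of squares of the absolute component uncertainties divided by the
#' total: sqrt(sum((c_i * u_i)^2)) / sum(c_i). Components with zero
#' contribution drop out.
#'
#' @param contributions Non-negative component magnitudes (same units).
#' @param rel_uncertainties Positive relative uncertainties, one per
#'   component.
#' @return Combined relative uncertainty, or `NA` (with attribute
#'   `undefined = TRUE`) if the total contribution is zero.
#' @export
#' @examples
#' combine_uncertainties(c(1, 1), c(0.3, 0.4))  # 0.25
combine_uncertainties <- function(contributions, rel_uncertainties) {
  if (any(contributions < 0)) abort_data("contributions must be >= 0")
  if (any(rel_uncertainties[contributions > 0] <= 0, na.rm = TRUE)) {
    abort_config("relative uncertainties must be positive")
  }
  total <- sum(contributions)
  if (total == 0) return(structure(NA_real_, undefined = TRUE))
  keep <- contributions > 0
  sqrt(sum((contributions[keep] * rel_uncertainties[keep])^2)) / total
}

#' Convert carbon pools to a CO2-equivalent density with uncertainty
#'
#' Biomass pools are converted to carbon by the 0.47 stoichiometric factor
#' and all carbon to CO2e by the 3.67 molar-mass factor; soil organic carbon
#' is already carbon so only the molar conversion applies. Belowground
#' biomass is weighted by a decay weight `min(1, horizon / 10)` reflecting a
#' conservative 10-year decay of the belowground pool after deforestation
#' (the default 10-year horizon counts it in full). Densities are returned
#' per km2 (1 Mg/ha = 100 t/km2) and the relative uncertainty is the
#' quadrature combination of the pool contributions.
#'
#' @param agb_biomass,bgb_biomass Biomass densities (Mg/ha).
#' @param soc_carbon Soil organic carbon density (Mg C/ha).
#' @param agb_u,bgb_u,soc_u Per-pool relative uncertainties (positive).
#' @param horizon_years Accounting horizon driving the belowground decay
#'   weight (default 10).
#' @param soc_weight Weight applied to the SOC pool (default 1, fully
#'   counted).
#' @return One-row tibble: `co2e_t_per_km2`, `rel_uncertainty`,
#'   `decay_weight`.
#' @export
#' @examples
#' pools_to_co2e(100, 0, 0, 0.2, 0.2, 0.2)$co2e_t_per_km2  # 17249
pools_to_co2e <- function(agb_biomass, bgb_biomass, soc_carbon,
                          agb_u, bgb_u, soc_u,
                          horizon_years = 10, soc_weight = 1) {
  if (any(c(agb_biomass, bgb_biomass, soc_carbon) < 0)) {
    abort_data("pool densities must be >= 0")
  }
  w_bgb <- min(1, horizon_years / 10)
  contrib <- c(
    agb = 3.67 * 0.47 * agb_biomass,
    bgb = 3.67 * 0.47 * w_bgb * bgb_biomass,
    soc = 3.67 * soc_weight * soc_carbon
  )
  u <- combine_uncertainties(contrib, c(agb_u, bgb_u, soc_u))
  tibble::tibble(
    co2e_t_per_km2 = 100 * sum(contrib),
    rel_uncertainty = as.numeric(u),
    decay_weight = w_bgb
  )
}

#' Build carbon estimates for method combinations
#'
#' Assembles, for every jurisdiction and every requested combination of
#' (forest-mask variant, AGB source, BGB source, SOC source), the pooled
#' CO2e density and its quadrature-propagated relative uncertainty. When the
#' BGB source is the ratio type, belowground biomass is derived from the
#' selected AGB source's density and the product's relative uncertainty
#' combines the AGB and ratio uncertainties in quadrature.
#'
#' @param carbon_layers Output of [generate_carbon_layers()].
#' @param carbon_grid Tibble of combinations with columns `carbon_mask_variant`,
#'   `agb_source`, `bgb_source`, `soc_source` (built if `NULL` from all
#'   levels present in `carbon_layers`).
#' @param horizon_years,soc_weight Passed to [pools_to_co2e()].
#' @return Tibble with one row per jurisdiction x combination:
#'   `co2e_t_per_km2`, `rel_uncertainty`, `agb_rel_u`, `bgb_rel_u`.
#' @export
estimate_carbon <- function(carbon_layers, carbon_grid = NULL,
                            horizon_years = 10, soc_weight = 1) {
  if (is.null(carbon_grid)) {
    carbon_grid <- tidyr::expand_grid(
      carbon_mask_variant = unique(carbon_layers$mask_variant),
      agb_source = unique(carbon_layers$source[carbon_layers$pool == "agb"]),
      bgb_source = unique(carbon_layers$source[carbon_layers$pool == "bgb"]),
      soc_source = unique(carbon_layers$source[carbon_layers$pool == "soc"])
    )
  }
  w_bgb <- min(1, horizon_years / 10)
  long <- carbon_layers |>
    dplyr::select("jurisdiction_id", "mask_variant", "source", "type",
                  "density_mg_ha", "ratio", "rel_uncertainty")

  pick <- function(source_col) {
    dplyr::inner_join(
      carbon_grid |> dplyr::mutate(source = .data[[source_col]]),
      long, by = c(carbon_mask_variant = "mask_variant", "source"),
      relationship = "many-to-many"
    )
  }
  agb <- pick("agb_source") |>
    dplyr::select("jurisdiction_id", "carbon_mask_variant", "agb_source",
                  "bgb_source", "soc_source",
                  agb_mg_ha = "density_mg_ha", agb_u = "rel_uncertainty")
  bgb <- pick("bgb_source") |>
    dplyr::select("jurisdiction_id", "carbon_mask_variant", "agb_source",
                  "bgb_source", "soc_source", bgb_type = "type",
                  bgb_mg_ha = "density_mg_ha", bgb_ratio = "ratio",
                  bgb_u0 = "rel_uncertainty")
  soc <- pick("soc_source") |>
    dplyr::select("jurisdiction_id", "carbon_mask_variant", "agb_source",
                  "bgb_source", "soc_source",
                  soc_mg_ha = "density_mg_ha", soc_u = "rel_uncertainty")

  keys <- c("jurisdiction_id", "carbon_mask_variant",
            "agb_source", "bgb_source", "soc_source")
  df <- agb |>
    dplyr::inner_join(bgb, by = keys) |>
    dplyr::inner_join(soc, by = keys) |>
    dplyr::mutate(
      bgb_mg_ha = dplyr::if_else(.data$bgb_type == "ratio",
                                 .data$agb_mg_ha * .data$bgb_ratio,
                                 .data$bgb_mg_ha),
      bgb_u = dplyr::if_else(.data$bgb_type == "ratio",
                             sqrt(.data$agb_u^2 + .data$bgb_u0^2),
                             .data$bgb_u0)
    )

  c_agb <- 3.67 * 0.47 * df$agb_mg_ha
  c_bgb <- 3.67 * 0.47 * w_bgb * df$bgb_mg_ha
  c_soc <- 3.67 * soc_weight * df$soc_mg_ha
  total <- c_agb + c_bgb + c_soc
  quad <- sqrt((c_agb * df$agb_u)^2 + (c_bgb * df$bgb_u)^2 + (c_soc * df$soc_u)^2)
  df |>
    dplyr::transmute(
      .data$jurisdiction_id, .data$carbon_mask_variant,
      .data$agb_source, .data$bgb_source, .data$soc_source,
      co2e_t_per_km2 = 100 * total,
      rel_uncertainty = dplyr::if_else(total > 0, quad / total, NA_real_),
      agb_rel_u = .data$agb_u, bgb_rel_u = .data$bgb_u,
      decay_weight = w_bgb
    )
}
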
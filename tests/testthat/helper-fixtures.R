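# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# medium cohort with default study conditions
fixture_sim <- function() {
  memo("sim_default", generate_panels(generator_config(
    n_jurisdictions = 40, seed = 101, n_children = 2)))
}

# low-noise cohort for parameter-recovery checks: common intercept (no
# forest-area spread), weak i.i.d. year noise, four equal planted effects
recovery_config <- function(seed) {
  generator_config(
    n_jurisdictions = 200, seed = seed, n_children = 0,
    forest_area_sdlog = 0,
    driver_effects = c(gdp = 0.15, pop_density = 0.15,
                       slope = -0.15, pct_agriculture = 0.15),
    ar1_coefficient = 0, ar1_sd = 0.05,
    variants = dplyr::mutate(default_variants(), obs_cv = 0.03)[2, ])
}

active_drivers <- c("gdp", "pop_density", "slope", "pct_agriculture")

# stationary, noise-free, homogeneous cohort: every jurisdiction's rate is
# the same constant in every year and every variant
constant_rate_config <- function(n = 120, seed = 7) {
  v <- default_variants()
  v$obs_cv <- 0
  v$bias <- 1
  generator_config(
    n_jurisdictions = n, seed = seed, n_children = 0,
    forest_area_sdlog = 0, driver_effects = c(gdp = 0),
    ar1_coefficient = 0, ar1_sd = 0, variants = v)
}

# hand-built three-unit cohort exercising each screening rule
screening_fixture <- function() {
  cfg <- generator_config(n_jurisdictions = 1, seed = 1)
  ref_year <- 2001
  mk_panel <- function(id, forest) {
    tibble::tibble(jurisdiction_id = id, variant = "modis",
                   year = ref_year, forest_km2 = forest, defor_km2 = NA_real_)
  }
  jur <- tibble::tibble(
    jurisdiction_id = c("small", "mid", "big", "big-1", "big-2", "big-3"),
    parent_id = c(NA, NA, NA, "big", "big", "big"),
    admin_level = c("national", "national", "national",
                    "subnational", "subnational", "subnational"),
    region = "Asia",
    land_area_km2 = c(5000, 20000, 60000, 15000, 25000, 15000))
  panels <- dplyr::bind_rows(
    mk_panel("small", 500), mk_panel("mid", 5000), mk_panel("big", 15000),
    mk_panel("big-1", 0.40 * 15000),  # 40% cover
    mk_panel("big-2", 0.12 * 25000),  # 12% cover
    mk_panel("big-3", 0.08 * 15000))  # 8% cover
  list(jurisdictions = jur, panels = panels,
       drivers = tibble::tibble(jurisdiction_id = character(0)),
       ground_truth = list(latent = tibble::tibble(jurisdiction_id = character(0)),
                           jurisdiction_truth = tibble::tibble(jurisdiction_id = character(0))),
       config = cfg)
}

expect_no_error <- function(expr) expect_error(expr, NA)

# constructed record sets with planted effect structure
planted_records <- function(n, seed, effects = c(approach = 1.0,
                                                 defor_variant = 0.35,
                                                 ref_length = 0.15,
                                                 agb_source = 0.03,
                                                 bgb_source = 0.03,
                                                 soc_source = 0.03,
                                                 carbon_mask_variant = 0.03),
                            noise_sd = 0.05) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      approach = sample(c("hist", "linear", "poly2", "global", "global_s",
                          "regional", "regional_s"), n, TRUE),
      defor_variant = sample(default_variants()$variant, n, TRUE),
      ref_length = sample(5:15, n, TRUE),
      carbon_mask_variant = sample(default_variants()$variant, n, TRUE),
      agb_source = sample(c("spawn_agb", "gedi_agb", "soto_agb"), n, TRUE),
      bgb_source = sample(c("spawn_bgb", "soto_bgb", "ipcc_bgb"), n, TRUE),
      soc_source = sample(c("esdac_soc", "olm_soc"), n, TRUE))
    lev_effect <- function(x, size) {
      levs <- sort(unique(x))
      size * (match(x, levs) - 1) / max(length(levs) - 1, 1)
    }
    log_b <- 10 +
      lev_effect(df$approach, effects["approach"]) +
      lev_effect(df$defor_variant, effects["defor_variant"]) +
      lev_effect(as.character(df$ref_length), effects["ref_length"]) +
      lev_effect(df$agb_source, effects["agb_source"]) +
      lev_effect(df$bgb_source, effects["bgb_source"]) +
      lev_effect(df$soc_source, effects["soc_source"]) +
      lev_effect(df$carbon_mask_variant, effects["carbon_mask_variant"]) +
      stats::rnorm(n, 0, noise_sd)
    dplyr::mutate(df, baseline_tco2e = exp(log_b), valid = TRUE)
  })
}

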
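test_that("combination enumeration follows the product rule and window fit", {
  v <- default_variants()
  cfg4 <- grid_config(approaches = c("hist", "linear"),
                      defor_variants = c("hansen30", "esacci"),
                      ref_lengths = 5, n_start_years = 1,
                      carbon_mask_variants = "modis", agb_sources = "spawn_agb",
                      bgb_sources = "ipcc_bgb", soc_sources = "esdac_soc")
  expect_equal(nrow(enumerate_combinations(cfg4, v)), 4)
  # annual loss is observable from the year after the first mapped year, so a
  # 2000-2021 span has 21 rate years and 21 - 15 + 1 = 7 valid 15-yr starts
  cfg15 <- grid_config(approaches = "hist", defor_variants = "hansen30",
                       ref_lengths = 15, n_start_years = NULL,
                       carbon_mask_variants = "modis", agb_sources = "spawn_agb",
                       bgb_sources = "ipcc_bgb", soc_sources = "esdac_soc")
  e <- enumerate_combinations(cfg15, v)
  expect_equal(nrow(e), 7)
  expect_equal(range(e$start_year), c(2001, 2007))
  expect_error(grid_config(approaches = character(0)),
               class = "deforbase_config_error")
})

test_that("the full-grid count matches a brute-force loop oracle at 1e9 scale", {
  v <- default_variants()
  full <- grid_config(ref_lengths = 5:15, n_start_years = NULL)
  n_pkg <- nrow(enumerate_combinations(full, v))
  # independent loop count: approaches x window cells x carbon combinations
  n_windows <- 0
  for (i in seq_len(nrow(v))) {
    n_rate_years <- v$last_year[i] - v$first_year[i]
    for (L in 5:15) n_windows <- n_windows + (n_rate_years - L + 1)
  }
  n_oracle <- 7 * n_windows * (5 * 3 * 3 * 2)
  expect_equal(n_pkg, n_oracle)
  # across the published cohort of 2,794 jurisdictions the grid reaches the
  # 1e9 order of magnitude
  total <- as.numeric(n_oracle) * 2794
  expect_gte(total, 1e9)
  expect_lt(total, 1e10)
})

test_that("uncertainty propagation is exact quadrature with correct limits", {
  expect_equal(propagate_uncertainty(0.3, 0.4), 0.5)
  expect_equal(propagate_uncertainty(0.25, 1e-12), 0.25, tolerance = 1e-6)
  expect_true(is.na(propagate_uncertainty(NA_real_, 0.3)))
  expect_error(propagate_uncertainty(-0.1, 0.3), class = "deforbase_data_error")
})

test_that("propagated uncertainty matches the product-distribution Monte Carlo", {
  withr::with_seed(55, {
    for (u in list(c(0.1, 0.2), c(0.3, 0.15), c(0.05, 0.3))) {
      draws <- (1 + stats::rnorm(1e5) * u[1]) * (1 + stats::rnorm(1e5) * u[2])
      mc_cv <- stats::sd(draws) / mean(draws)
      expect_equal(propagate_uncertainty(u[1], u[2]), mc_cv, tolerance = 0.10)
    }
  })
})

test_that("baseline records are the rate-density product and respect validity", {
  proj <- tibble::tibble(
    jurisdiction_id = "J1", approach = c("linear", "linear", "hist"),
    defor_variant = "hansen30", ref_length = 5L, start_year = 2005L,
    point_rate = c(10, -3, 4), pi_lower = c(8, -5, NA), pi_upper = c(12, 1, NA),
    rel_uncertainty = c(0.2, 1, NA), valid = c(TRUE, TRUE, TRUE)) |>
    screen_nonnegative()
  carb <- tibble::tibble(
    jurisdiction_id = "J1", carbon_mask_variant = "modis",
    agb_source = "spawn_agb", bgb_source = "ipcc_bgb", soc_source = "esdac_soc",
    co2e_t_per_km2 = 17249, rel_uncertainty = 0.1,
    agb_rel_u = 0.15, bgb_rel_u = 0.36, decay_weight = 1)
  bl <- compute_baseline(proj, carb)
  expect_equal(nrow(bl), 3)
  expect_equal(bl$baseline_tco2e[1], 172490)
  expect_false(bl$valid[2])                   # negative projection excluded
  expect_true(is.na(bl$baseline_tco2e[2]))
  expect_equal(bl$propagated_rel_u[1], sqrt(0.2^2 + 0.1^2))
  expect_true(is.na(bl$propagated_rel_u[3]))  # hist carries no rate term
  expect_true(all(bl$baseline_tco2e[bl$valid] >= 0))
})

test_that("the grid engine emits one record per jurisdiction and combination", {
  sim <- fixture_sim()
  scr <- screen_jurisdictions(sim)
  layers <- generate_carbon_layers(sim$config, scr)
  gcfg <- grid_config(approaches = c("hist", "linear"),
                      defor_variants = c("hansen30", "modis"),
                      ref_lengths = c(5, 10), n_start_years = 2,
                      carbon_mask_variants = "modis",
                      agb_sources = c("spawn_agb", "gedi_agb"),
                      bgb_sources = "ipcc_bgb", soc_sources = "esdac_soc")
  bl <- run_grid(scr, layers, gcfg, seed = 2)
  combos <- enumerate_combinations(gcfg, sim$config$variants)
  n_jur <- dplyr::n_distinct(scr$jurisdictions$jurisdiction_id)
  expect_equal(nrow(bl), nrow(combos) * n_jur)
  expect_equal(dplyr::n_distinct(bl$combination_id), nrow(combos))
  # determinism ignoring row order
  bl2 <- run_grid(scr, layers, gcfg, seed = 2)
  ord <- function(x) dplyr::arrange(x, jurisdiction_id, combination_id)
  expect_equal(ord(bl), ord(bl2))
  # chunked execution returns the same records
  bl3 <- run_grid(scr, layers, gcfg, seed = 2, chunk_size = 3)
  expect_equal(ord(bl), ord(dplyr::as_tibble(bl3)))
})

test_that("baselines scale linearly with carbon density", {
  sim <- fixture_sim()
  scr <- screen_jurisdictions(sim)
  layers <- generate_carbon_layers(sim$config, scr)
  gcfg <- grid_config(approaches = "hist", defor_variants = "hansen30",
                      ref_lengths = 5, n_start_years = 1,
                      carbon_mask_variants = "hansen30",
                      agb_sources = c("spawn_agb", "soto_agb"),
                      bgb_sources = c("spawn_bgb", "ipcc_bgb"),
                      soc_sources = "olm_soc")
  bl1 <- run_grid(scr, layers, gcfg, seed = 1)
  scaled <- dplyr::mutate(layers, density_mg_ha = 2 * density_mg_ha)
  bl2 <- run_grid(scr, scaled, gcfg, seed = 1)
  expect_equal(bl2$baseline_tco2e, 2 * bl1$baseline_tco2e, tolerance = 1e-12)
})

test_that("the grid engine's fast path matches the single-series operations", {
  sim <- fixture_sim()
  gcfg <- grid_config(approaches = c("hist", "linear", "poly2"),
                      defor_variants = "esacci", ref_lengths = 8,
                      n_start_years = 1, carbon_mask_variants = "modis",
                      agb_sources = "spawn_agb", bgb_sources = "ipcc_bgb",
                      soc_sources = "esdac_soc")
  proj <- run_projections(sim, gcfg, seed = 1)
  start <- proj$start_year[1]
  for (id in sim$jurisdictions$jurisdiction_id[1:5]) {
    ser <- dplyr::filter(sim$panels, jurisdiction_id == id, variant == "esacci")
    for (case in list(list("hist", function(d) project_historical_average(d, start, 8)),
                      list("linear", function(d) project_time_function(d, start, 8, 1)),
                      list("poly2", function(d) project_time_function(d, start, 8, 2)))) {
      ref <- screen_nonnegative(case[[2]](ser))  # grid output is post-screening
      got <- dplyr::filter(proj, jurisdiction_id == id, approach == case[[1]])
      expect_equal(got$point_rate, ref$point_rate, tolerance = 1e-10)
      expect_equal(got$pi_lower, ref$pi_lower, tolerance = 1e-10)
      expect_equal(got$rel_uncertainty, ref$rel_uncertainty, tolerance = 1e-10)
    }
  }
})
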
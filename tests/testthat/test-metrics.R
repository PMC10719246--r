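test_that("relative variability follows the CV definition", {
  expect_equal(relative_variability(c(1, 2, 3)), 50)  # sd 1, mean 2
  expect_equal(relative_variability(rep(4, 10)), 0)
  expect_true(is.na(relative_variability(c(-2, 1))))  # non-positive mean
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- stats::rlnorm(20)
      k <- stats::runif(1, 0.1, 50)
      expect_equal(relative_variability(k * x), relative_variability(x),
                   tolerance = 1e-10)
    }
  })
})

test_that("per-level CVs equal a filter-then-formula oracle and decompose variance", {
  withr::with_seed(14, {
    bl <- tidyr::expand_grid(
      jurisdiction_id = c("A", "B"),
      approach = c("m1", "m2"),
      ref_length = c(5L, 10L),
      rep = 1:5) |>
      dplyr::mutate(baseline_tco2e = stats::rlnorm(dplyr::n(), 10, 0.3),
                    valid = TRUE)
  })
  per <- per_level_variability(bl, "approach")
  for (j in c("A", "B")) {
    for (lv in c("m1", "m2")) {
      sub <- bl$baseline_tco2e[bl$jurisdiction_id == j & bl$approach == lv]
      expect_equal(per$cv_percent[per$jurisdiction_id == j & per$level == lv],
                   100 * stats::sd(sub) / mean(sub), tolerance = 1e-10)
    }
  }
  # a parameter with a single level reproduces the overall CV
  one <- per_level_variability(dplyr::mutate(bl, variant = "only"), "variant")
  ov <- overall_variability(bl)
  expect_equal(dplyr::arrange(one, jurisdiction_id)$cv_percent,
               dplyr::arrange(ov, jurisdiction_id)$cv_percent)
  # construction where one approach doubles baselines: fixing either level
  # removes the between-level spread, so each per-level CV < overall CV
  bl2 <- dplyr::mutate(bl, baseline_tco2e = ifelse(approach == "m2",
                                                   2 * baseline_tco2e,
                                                   baseline_tco2e))
  per2 <- per_level_variability(bl2, "approach")
  ov2 <- overall_variability(bl2)
  cmp <- dplyr::inner_join(per2, ov2, by = "jurisdiction_id")
  expect_true(all(cmp$cv_percent.x < cmp$cv_percent.y))
})

test_that("hindcast forecast error is the relative deviation from the ensuing window", {
  # stationary noise-free series: the historical average hindcasts perfectly
  sim <- generate_panels(constant_rate_config(n = 3, seed = 5))
  fe <- hindcast_evaluate(sim, "J0001", "hist", "hansen30", 2002, 8)
  expect_equal(fe$forecast_error, 0, tolerance = 1e-12)
  # doubling construction through the same code path
  sim2 <- sim
  sim2$panels <- sim2$panels |>
    dplyr::mutate(defor_km2 = ifelse(year >= 2010, defor_km2 / 2, defor_km2))
  fe2 <- hindcast_evaluate(sim2, "J0001", "hist", "hansen30", 2002, 8)
  expect_equal(fe2$forecast_error, 1, tolerance = 1e-9)  # predicted = 2 x actual
  # zero actual rates are excluded with a reason, not infinite errors
  sim3 <- sim
  sim3$panels <- sim3$panels |>
    dplyr::mutate(defor_km2 = ifelse(year >= 2010, 0, defor_km2))
  fe3 <- hindcast_evaluate(sim3, "J0001", "hist", "hansen30", 2002, 8)
  expect_true(is.na(fe3$forecast_error))
  expect_identical(fe3$reason, "zero actual rate")
})

test_that("uncertainty summaries report medians and exceedance fractions", {
  bl <- tibble::tibble(
    jurisdiction_id = "J", approach = c("linear", "linear", "hist"),
    propagated_rel_u = c(0.10, 0.20, NA), rate_rel_u = c(0.08, 0.18, NA),
    carbon_rel_u = c(0.06, 0.06, 0.06), agb_rel_u = 0.05, bgb_rel_u = 0.33,
    valid = TRUE)
  us <- uncertainty_summaries(bl, threshold = 15)
  b <- dplyr::filter(us, component == "baseline")
  expect_equal(b$median_rel_uncertainty_pct, 15)  # median of 10% and 20%
  expect_equal(b$fraction_exceeding, 0.5)
  expect_equal(b$n_methods, 2)  # hist excluded from the propagated pool
  expect_equal(dplyr::filter(us, component == "carbon")$fraction_exceeding, 0)
  # monotone non-increasing in the threshold
  withr::with_seed(6, {
    pool <- tibble::tibble(jurisdiction_id = "X", approach = "linear",
                           propagated_rel_u = stats::runif(50, 0, 0.5),
                           rate_rel_u = 0.1, carbon_rel_u = 0.1,
                           agb_rel_u = 0.1, bgb_rel_u = 0.1, valid = TRUE)
    fr <- vapply(c(5, 10, 20, 40), function(th) {
      dplyr::filter(uncertainty_summaries(pool, th),
                    component == "baseline")$fraction_exceeding
    }, numeric(1))
    expect_true(all(diff(fr) <= 0))
  })
})

test_that("level comparison degenerates correctly on identical groups", {
  dat <- tibble::tibble(level = rep(c("a", "b", "c"), each = 20),
                        cv_percent = rep(stats::rnorm(20, 50, 5), 3))
  cmp <- compare_levels(dat)
  expect_lt(cmp$anova$statistic, 1e-20)
  expect_true(all(cmp$tukey$adj_p_value > 0.999))
  expect_equal(nrow(cmp$tukey), 3)  # all level pairs reported
  expect_error(compare_levels(tibble::tibble(level = "a", cv_percent = 1:5)),
               class = "deforbase_data_error")
  g <- glance(cmp)
  expect_equal(g$df_between, 2)
  expect_equal(g$df_within, 57)
})

test_that("area-variability correlation matches the closed form and the null", {
  areas <- exp(seq(4, 10, length.out = 30))
  dat <- tibble::tibble(forest_km2 = areas, cv_percent = -log(areas) * 3 + 100)
  r <- area_variability_correlation(dat)
  expect_equal(r$pearson_r, -1, tolerance = 1e-12)
  withr::with_seed(9, {
    x <- stats::rlnorm(40, 8, 1)
    y <- stats::runif(40, 20, 90)
    dat2 <- tibble::tibble(forest_km2 = x, cv_percent = y)
    r2 <- area_variability_correlation(dat2)
    # brute-force covariance formula
    lx <- log(x)
    oracle <- sum((lx - mean(lx)) * (y - mean(y))) /
      sqrt(sum((lx - mean(lx))^2) * sum((y - mean(y))^2))
    expect_equal(r2$pearson_r, oracle, tolerance = 1e-10)
    # permutation null centred on zero
    rs <- vapply(1:500, function(i) {
      area_variability_correlation(
        tibble::tibble(forest_km2 = x, cv_percent = sample(y)))$pearson_r
    }, numeric(1))
    expect_lt(abs(mean(rs)), 0.05)
  })
  expect_error(area_variability_correlation(
    tibble::tibble(forest_km2 = c(1, 2, 3), cv_percent = c(5, 5, 5))),
    class = "deforbase_data_error")
})
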
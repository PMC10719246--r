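test_that("historical average equals a brute-force mean on random windows", {
  expect_equal(project_historical_average(
    tibble::tibble(year = 1:3, defor_km2 = c(10, 12, 14)), 1, 3)$point_rate, 12)
  expect_equal(project_historical_average(
    tibble::tibble(year = 1:8, defor_km2 = rep(5, 8)), 2, 6)$point_rate, 5)
  withr::with_seed(1, {
    for (i in 1:100) {
      y <- stats::rlnorm(30)
      d <- tibble::tibble(year = 2000 + 0:29, defor_km2 = y)
      s <- sample(0:20, 1)
      # independent oracle: explicit summation loop
      acc <- 0
      for (k in 0:9) acc <- acc + y[s + k + 1]
      expect_equal(project_historical_average(d, 2000 + s, 10)$point_rate,
                   acc / 10, tolerance = 1e-12)
    }
  })
  expect_error(project_historical_average(
    tibble::tibble(year = 1:3, defor_km2 = 1:3), 2, 5),
    class = "deforbase_range_error")
})

test_that("time functions reproduce noiseless polynomials and project their mean", {
  d <- tibble::tibble(year = 0:9, defor_km2 = 2 + 1 * (0:9))
  r <- project_time_function(d, 0, 10, degree = 1)
  expect_equal(r$point_rate, 16.5, tolerance = 1e-9)  # mean of t = 10..19 fits
  expect_lt(r$pi_upper - r$pi_lower, 1e-8)
  q <- tibble::tibble(year = 0:9, defor_km2 = 3 - 0.5 * (0:9) + 0.2 * (0:9)^2)
  fitq <- stats::lm(defor_km2 ~ poly(year, 2, raw = TRUE), data = q)
  expect_equal(unname(stats::fitted(fitq)), q$defor_km2, tolerance = 1e-9)
  rq <- project_time_function(q, 0, 10, degree = 2)
  tf <- 10:19
  expect_equal(rq$point_rate, mean(3 - 0.5 * tf + 0.2 * tf^2), tolerance = 1e-8)
})

test_that("linear/poly2 coefficients match a normal-equations oracle", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(8:15, 1)
      deg <- sample(1:2, 1)
      y <- stats::rlnorm(n, meanlog = 2)
      t0 <- 0:(n - 1)
      X <- cbind(1, stats::poly(t0, degree = deg, raw = TRUE))
      beta_oracle <- unname(drop(solve(t(X) %*% X, t(X) %*% y)))
      d <- tibble::tibble(year = 2000 + t0, defor_km2 = y)
      fit <- stats::lm(y ~ stats::poly(t0, degree = deg, raw = TRUE))
      expect_equal(unname(stats::coef(fit)), beta_oracle, tolerance = 1e-8)
      # and the package's projection equals the oracle's horizon mean
      tf <- n:(2 * n - 1)
      Xf <- cbind(1, stats::poly(tf, degree = deg, raw = TRUE))
      expect_equal(project_time_function(d, 2000, n, deg)$point_rate,
                   mean(drop(Xf %*% beta_oracle)), tolerance = 1e-8)
    }
  })
})

test_that("driver-model prediction equals the matrix-arithmetic oracle on the transformed scale", {
  sim <- fixture_sim()
  m <- fit_driver_model(sim, "global", "hansen30", 2005, 10)
  nd <- driver_window_means(sim$drivers, 2005, 10)
  z_pkg <- stats::predict(m$fit, newdata = nd)
  X <- cbind(1, as.matrix(nd[, m$drivers_retained]))
  beta <- stats::coef(m$fit)[c("(Intercept)", m$drivers_retained)]
  expect_equal(unname(z_pkg), drop(X %*% beta), tolerance = 1e-8)
  # regression through the mean: prediction at the fit-sample mean drivers
  # equals the back-transformed mean transformed response
  fit_dat <- m$fit$model
  mean_x <- tibble::as_tibble(as.list(colMeans(fit_dat[, m$drivers_retained, drop = FALSE])))
  mean_x$jurisdiction_id <- "mean"
  pr <- predict_driver_model(m, mean_x)
  expect_equal(pr$point_rate,
               max(deforbase:::bc_inverse(mean(fit_dat$y_bc), m$lambda) - m$offset, 0),
               tolerance = 1e-8)
})

test_that("back-transformed intervals stay ordered for lambdas across [-2, 2]", {
  withr::with_seed(3, {
    for (lam in seq(-2, 2, by = 0.25)) {
      y <- sort(stats::rlnorm(1000, meanlog = 1, sdlog = 1))
      z <- deforbase:::bc_transform(y, lam)
      expect_true(all(diff(z) > 0), info = paste("lambda =", lam))
      # round trip through the inverse preserves order and values
      expect_equal(deforbase:::bc_inverse(z, lam), y, tolerance = 1e-8)
    }
  })
  sim <- fixture_sim()
  m <- fit_driver_model(sim, "global", "esacci", 2000, 8)
  pr <- predict_driver_model(m, driver_window_means(sim$drivers, 2000, 8))
  expect_true(all(pr$pi_lower <= pr$point_rate + 1e-9))
  expect_true(all(pr$point_rate <= pr$pi_upper + 1e-9))
})

test_that("under-determined scopes refuse to fit", {
  sim <- fixture_sim()
  regions <- dplyr::count(sim$jurisdictions, region)
  small <- regions$region[which.min(regions$n)]
  if (min(regions$n) < 17) {
    expect_error(fit_driver_model(sim, small, "hansen30", 2005, 10),
                 class = "deforbase_fit_error")
  }
  expect_error(
    fit_driver_model(list(jurisdictions = sim$jurisdictions[1:3, ],
                          panels = sim$panels, drivers = sim$drivers),
                     "global", "hansen30", 2005, 10),
    class = "deforbase_fit_error")
})

test_that("noiseless single-driver data are recovered almost exactly", {
  cfg <- generator_config(
    n_jurisdictions = 60, seed = 13, n_children = 0, forest_area_sdlog = 0,
    driver_effects = c(gdp = 0.5), ar1_coefficient = 0, ar1_sd = 0,
    variants = dplyr::mutate(default_variants(), obs_cv = 0, bias = 1)[2, ])
  sim <- generate_panels(cfg)
  m <- fit_driver_model(sim, "global", "hansen30", 2005, 10, drivers = "gdp")
  pr <- predict_driver_model(m, driver_window_means(sim$drivers, 2005, 10))
  lat <- sim$ground_truth$latent |>
    dplyr::filter(year >= 2005, year <= 2014) |>
    dplyr::group_by(jurisdiction_id) |>
    dplyr::summarise(lat = mean(latent_rate_km2), .groups = "drop")
  cmp <- dplyr::inner_join(pr, lat, by = "jurisdiction_id")
  expect_lt(stats::median(abs(cmp$point_rate - cmp$lat) / cmp$lat), 0.01)
  # ensemble whose members all see the full driver set recovers it too
  ens <- ensemble_predict(sim, "global", "hansen30", 2005, 10, reps = 5,
                          size_range = c(12, 12), seed = 2)
  cmp2 <- dplyr::inner_join(ens, lat, by = "jurisdiction_id")
  expect_lt(stats::median(abs(cmp2$point_rate - cmp2$lat) / cmp2$lat), 0.01)
})

test_that("ensembles are deterministic and collapse to the full model with one member", {
  sim <- fixture_sim()
  a <- ensemble_predict(sim, "global", "hansen30", 2005, 10, reps = 8, seed = 4)
  b <- ensemble_predict(sim, "global", "hansen30", 2005, 10, reps = 8, seed = 4)
  expect_identical(a, b)
  full <- predict_driver_model(
    fit_driver_model(sim, "global", "hansen30", 2005, 10),
    driver_window_means(sim$drivers, 2005, 10) |>
      dplyr::filter(jurisdiction_id %in% sim$jurisdictions$jurisdiction_id))
  one <- ensemble_predict(sim, "global", "hansen30", 2005, 10, reps = 1,
                          size_range = c(12, 12), seed = 4)
  cmp <- dplyr::inner_join(full, one, by = "jurisdiction_id")
  expect_equal(cmp$point_rate.x, cmp$point_rate.y, tolerance = 1e-10)
  # too few jurisdictions for any member: ensemble error
  tiny <- list(jurisdictions = sim$jurisdictions[1:4, ],
               panels = sim$panels, drivers = sim$drivers)
  expect_error(ensemble_predict(tiny, "global", "hansen30", 2005, 10,
                                reps = 4, seed = 1),
               class = "deforbase_fit_error")
})

test_that("non-negativity screening excludes negatives and floors intervals", {
  res <- tibble::tibble(
    approach = "linear",
    point_rate = c(-3, 0, 7), pi_lower = c(-5, -0.5, -1),
    pi_upper = c(1, 2, 9), rel_uncertainty = 1, valid = TRUE)
  scr <- screen_nonnegative(res)
  expect_identical(scr$valid, c(FALSE, TRUE, TRUE))
  expect_equal(scr$pi_lower[2:3], c(0, 0))
  expect_equal(scr$pi_lower[1], -5)  # invalid rows untouched, kept for audit
})

test_that("all approaches agree on a stationary noise-free cohort", {
  sim <- generate_panels(constant_rate_config(n = 30, seed = 21))
  const_rate <- sim$ground_truth$latent$latent_rate_km2[1]
  expect_equal(stats::sd(sim$ground_truth$latent$latent_rate_km2), 0)
  gcfg <- grid_config(approaches = c("hist", "linear", "poly2", "global", "global_s"),
                      defor_variants = "hansen30", ref_lengths = 10,
                      n_start_years = 1, ensemble_reps = 5)
  proj <- run_projections(sim, gcfg, seed = 3)
  valid <- dplyr::filter(proj, valid)
  expect_gt(nrow(valid), 0)
  expect_equal(valid$point_rate, rep(const_rate, nrow(valid)), tolerance = 1e-6)
})
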
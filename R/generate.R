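#' Generate synthetic jurisdiction panels with known ground truth
#'
#' Simulates, per national jurisdiction, a latent annual deforestation
#' process driven by covariates -- log latent rate = intercept +
#' sum(effects * drivers) + AR(1) noise -- and observes it through each
#' configured forest-dataset variant as latent rate x variant bias x
#' mean-preserving lognormal noise. Observed loss is then clipped so that no
#' year removes more forest than remained the year before, which also makes
#' every variant's forest-area series non-increasing. Each national
#' jurisdiction additionally gets subnational (level-1) children that
#' partition its latent series by a seeded Dirichlet share vector, so that
#' [screen_jurisdictions()] can substitute children for large nations.
#'
#' Identical `(config, seed)` regenerate bit-identical tables, and every
#' jurisdiction draws from its own named random stream, so enlarging
#' `n_jurisdictions` never perturbs previously generated jurisdictions.
#'
#' @param config A [generator_config()].
#' @return A list of class `defor_sim` with tibbles:
#'   `jurisdictions` (id, parent, admin level, region, land area),
#'   `panels` (jurisdiction, variant, year, forest_km2, defor_km2),
#'   `drivers` (jurisdiction, year, twelve covariates), and a `ground_truth`
#'   list holding the latent series, true driver coefficients and
#'   per-jurisdiction intercept terms.
#' @export
#' @examples
#' sim <- generate_panels(generator_config(n_jurisdictions = 3, seed = 42))
#' dplyr::count(sim$panels, variant)
generate_panels <- function(config) {
  validate_generator_config(config)
  v <- config$variants
  year_lo <- min(v$first_year) + 1L
  year_hi <- max(v$last_year)
  years <- seq.int(year_lo, year_hi)

  beta <- stats::setNames(numeric(12L), driver_names())
  beta[names(config$driver_effects)] <- config$driver_effects

  units <- vector("list", config$n_jurisdictions)
  for (j in seq_len(config$n_jurisdictions)) {
    units[[j]] <- generate_one_jurisdiction(config, j, years, beta)
  }

  sim <- list(
    jurisdictions = dplyr::bind_rows(purrr::map(units, "jurisdictions")),
    panels = dplyr::bind_rows(purrr::map(units, "panels")),
    drivers = dplyr::bind_rows(purrr::map(units, "drivers")),
    ground_truth = list(
      latent = dplyr::bind_rows(purrr::map(units, "latent")),
      coefficients = tibble::tibble(driver = driver_names(), effect = unname(beta)),
      jurisdiction_truth = dplyr::bind_rows(purrr::map(units, "truth"))
    ),
    config = config
  )
  class(sim) <- "defor_sim"
  sim
}

generate_one_jurisdiction <- function(config, j, years, beta) {
  id <- sprintf("J%04d", j)
  n_years <- length(years)

  meta <- with_stream_seed(stream_seed(config$seed, "jur", j, "meta"), {
    region <- sample(region_labels(), 1L)
    forest0 <- stats::rlnorm(1L,
      meanlog = log(config$forest_area_mean_km2) - config$forest_area_sdlog^2 / 2,
      sdlog = config$forest_area_sdlog)
    cover <- stats::runif(1L, 0.15, 0.85)
    list(region = region, forest0 = forest0, land = forest0 / cover)
  })

  # Dirichlet shares partition the national latent process among children;
  # land shares are drawn separately so child forest-cover fractions vary.
  ch <- with_stream_seed(stream_seed(config$seed, "jur", j, "children"), {
    k <- config$n_children
    if (k > 0) {
      s_rate <- stats::rgamma(k, shape = config$dirichlet_alpha)
      s_land <- stats::rgamma(k, shape = config$dirichlet_alpha)
      list(rate = s_rate / sum(s_rate), land = s_land / sum(s_land))
    } else {
      list(rate = numeric(0), land = numeric(0))
    }
  })

  drivers_parent <- with_stream_seed(stream_seed(config$seed, "jur", j, "drivers"), {
    draw_driver_panel(years)
  })

  latent_parent <- with_stream_seed(stream_seed(config$seed, "jur", j, "latent"), {
    x <- as.matrix(drivers_parent[, driver_names()])
    eta <- draw_ar1(n_years, config$ar1_coefficient, config$ar1_sd)
    exp(log(config$base_rate_fraction * meta$forest0) + drop(x %*% beta) + eta)
  })

  unit_ids <- c(id, if (config$n_children > 0) sprintf("%s-%d", id, seq_len(config$n_children)))
  unit_forest0 <- c(meta$forest0, ch$rate * meta$forest0)
  unit_land <- c(meta$land, ch$land * meta$land)
  unit_latent <- c(list(latent_parent),
                   purrr::map(ch$rate, function(s) s * latent_parent))

  jur_tbl <- tibble::tibble(
    jurisdiction_id = unit_ids,
    parent_id = c(NA_character_, rep(id, length(unit_ids) - 1L)),
    admin_level = c("national", rep("subnational", length(unit_ids) - 1L)),
    region = meta$region,
    land_area_km2 = unit_land
  )

  drv <- vector("list", length(unit_ids))
  drv[[1]] <- dplyr::mutate(drivers_parent, jurisdiction_id = id, .before = 1)
  if (length(unit_ids) > 1L) {
    for (k in 2:length(unit_ids)) {
      off <- with_stream_seed(stream_seed(config$seed, "jur", j, "child_drivers", k), {
        stats::rnorm(12L, 0, 0.3)
      })
      d <- drivers_parent
      d[driver_names()] <- sweep(as.matrix(d[, driver_names()]), 2L, off, `+`)
      drv[[k]] <- dplyr::mutate(d, jurisdiction_id = unit_ids[k], .before = 1)
    }
  }

  panels <- vector("list", length(unit_ids) * nrow(config$variants))
  p <- 0L
  for (k in seq_along(unit_ids)) {
    # noise CV may scale with unit forest area (pixel-counting estimators are
    # relatively noisier on small areas)
    area_scale <- (unit_forest0[k] / config$forest_area_mean_km2)^(-config$area_noise_exponent)
    for (vi in seq_len(nrow(config$variants))) {
      row <- config$variants[vi, ]
      p <- p + 1L
      panels[[p]] <- with_stream_seed(
        stream_seed(config$seed, "jur", j, "obs", unit_ids[k], row$variant), {
          observe_variant(unit_ids[k], row, unit_latent[[k]], years,
                          unit_forest0[k], row$obs_cv * area_scale)
        })
    }
  }

  list(
    jurisdictions = jur_tbl,
    panels = dplyr::bind_rows(panels),
    drivers = dplyr::bind_rows(drv),
    latent = dplyr::bind_rows(purrr::map2(
      unit_ids, unit_latent,
      function(u, l) tibble::tibble(jurisdiction_id = u, year = years, latent_rate_km2 = l))),
    truth = tibble::tibble(
      jurisdiction_id = unit_ids, region = meta$region,
      forest0_km2 = unit_forest0,
      log_intercept = log(config$base_rate_fraction * unit_forest0))
  )
}

# static N(0,1) level per driver; a subset varies over time with a slow AR(1)
# wiggle (climate, economy, demography, land-use shares)
draw_driver_panel <- function(years) {
  tv <- c("temperature", "precipitation", "gdp", "nightlights",
          "pop_density", "pct_forest", "pct_agriculture")
  base <- stats::rnorm(12L)
  names(base) <- driver_names()
  out <- matrix(rep(base, each = length(years)), nrow = length(years),
                dimnames = list(NULL, driver_names()))
  for (d in tv) {
    out[, d] <- out[, d] + draw_ar1(length(years), 0.9, 0.15)
  }
  dplyr::bind_cols(tibble::tibble(year = years), tibble::as_tibble(out))
}

# AR(1) with marginal (stationary) sd `sd_marg`
draw_ar1 <- function(n, rho, sd_marg) {
  if (sd_marg == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1L, 0, sd_marg)
  if (n > 1L) {
    inn <- stats::rnorm(n - 1L, 0, sd_marg * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1L] + inn[t - 1L]
  }
  e
}

# observe one variant: bias x mean-preserving lognormal noise, then clip each
# year's loss to the forest remaining the year before
observe_variant <- function(unit_id, vrow, latent, years, forest0, cv) {
  keep <- years >= (vrow$first_year + 1L) & years <= vrow$last_year
  yrs <- years[keep]
  lat <- latent[keep]
  if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    eps <- exp(stats::rnorm(length(lat), -s^2 / 2, s))
  } else {
    eps <- rep(1, length(lat))
  }
  obs <- lat * vrow$bias * eps
  forest_start <- forest0 * vrow$forest_scale
  forest <- numeric(length(yrs) + 1L)
  forest[1] <- forest_start
  defor <- numeric(length(yrs))
  for (t in seq_along(yrs)) {
    defor[t] <- min(obs[t], forest[t])
    forest[t + 1L] <- forest[t] - defor[t]
  }
  tibble::tibble(
    jurisdiction_id = unit_id,
    variant = vrow$variant,
    year = c(vrow$first_year, yrs),
    forest_km2 = forest,
    defor_km2 = c(NA_real_, defor)
  )
}

#' Generate per-source carbon density observations
#'
#' For every jurisdiction in `sim`, draws true mean aboveground biomass,
#' belowground biomass (a region-specific root:shoot ratio of AGB) and soil
#' organic carbon densities, then produces one observation per
#' (forest-mask variant, source): dense sources report truth x mask factor x
#' source bias; the sparse source simulates `n_cells` equal-area sub-units
#' and reports the mean over a sampled fraction with its uncertainty inflated
#' by the finite-sampling standard error; ratio-type BGB sources report the
#' root:shoot ratio to be applied to whichever AGB source a method
#' combination selects. Sources without a provider uncertainty receive the
#' 33% default (see [default_uncertainty()]).
#'
#' @param config A [generator_config()].
#' @param sim A `defor_sim` from [generate_panels()].
#' @return A tibble (jurisdiction_id, mask_variant, source, pool, type,
#'   density_mg_ha, ratio, rel_uncertainty) with the per-jurisdiction truth
#'   attached as attribute `"truth"`.
#' @export
generate_carbon_layers <- function(config, sim) {
  if (config$sparse_sampling_fraction <= 0) abort_config("sampling fraction must be > 0")
  src <- config$carbon_sources
  need <- table(src$pool)
  if ((need["agb"] %||% 0) < 3 || (need["bgb"] %||% 0) < 3 || (need["soc"] %||% 0) < 2) {
    abort_config("carbon_sources needs >= 3 AGB, >= 3 BGB (one ratio-type) and >= 2 SOC sources")
  }
  jur <- sim$jurisdictions
  out <- vector("list", nrow(jur))
  truth <- vector("list", nrow(jur))
  for (i in seq_len(nrow(jur))) {
    id <- jur$jurisdiction_id[i]
    parent <- jur$parent_id[i]
    base_id <- if (is.na(parent)) id else parent
    tr <- with_stream_seed(stream_seed(config$seed, "carbon_truth", base_id), {
      agb <- stats::rlnorm(1L, log(config$agb_mean) - config$agb_sdlog^2 / 2, config$agb_sdlog)
      soc <- stats::rlnorm(1L, log(config$soc_mean) - config$soc_sdlog^2 / 2, config$soc_sdlog)
      c(agb = agb, soc = soc)
    })
    if (!is.na(parent)) {
      pert <- with_stream_seed(stream_seed(config$seed, "carbon_truth", base_id, id), {
        exp(stats::rnorm(2L, 0, 0.15))
      })
      tr <- tr * pert
    }
    ratio <- config$bgb_ratios$ratio[match(jur$region[i], config$bgb_ratios$region)]
    true_bgb <- ratio * tr[["agb"]]
    truth[[i]] <- tibble::tibble(
      jurisdiction_id = id, true_agb_mg_ha = tr[["agb"]],
      true_bgb_mg_ha = true_bgb, true_soc_mg_ha = tr[["soc"]],
      true_bgb_ratio = ratio)
    out[[i]] <- with_stream_seed(stream_seed(config$seed, "carbon_obs", id), {
      observe_carbon_sources(config, id, tr[["agb"]], true_bgb, tr[["soc"]], ratio)
    })
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- dplyr::bind_rows(truth)
  res
}

observe_carbon_sources <- function(config, id, true_agb, true_bgb, true_soc, ratio) {
  src <- config$carbon_sources
  masks <- config$variants[, c("variant", "carbon_mask_factor")]
  rows <- tidyr::expand_grid(mask_variant = masks$variant, source = src$source)
  rows <- dplyr::left_join(rows, src, by = "source")
  rows <- dplyr::left_join(rows, dplyr::rename(masks, mask_variant = "variant"),
                           by = "mask_variant")
  pool_truth <- c(agb = true_agb, bgb = true_bgb, soc = true_soc)

  density <- numeric(nrow(rows))
  relu <- numeric(nrow(rows))
  ratio_col <- rep(NA_real_, nrow(rows))
  for (r in seq_len(nrow(rows))) {
    u0 <- default_uncertainty(rows$rel_uncertainty[r])
    if (rows$type[r] == "ratio") {
      density[r] <- NA_real_
      ratio_col[r] <- ratio
      relu[r] <- u0
    } else if (rows$type[r] == "sparse") {
      mu <- pool_truth[[rows$pool[r]]] * rows$carbon_mask_factor[r] * rows$bias[r]
      cells <- pmax(stats::rnorm(config$n_cells, mu, config$cell_cv * mu), 0)
      m <- max(1L, round(config$sparse_sampling_fraction * config$n_cells))
      idx <- sample_int(config$n_cells, m)
      est <- mean(cells[idx])
      if (m > 1L && est > 0) {
        fpc <- sqrt((config$n_cells - m) / (config$n_cells - 1))
        rel_se <- stats::sd(cells[idx]) / sqrt(m) * fpc / est
      } else {
        rel_se <- 0
      }
      density[r] <- est
      relu[r] <- sqrt(u0^2 + rel_se^2)
    } else {
      density[r] <- pool_truth[[rows$pool[r]]] * rows$carbon_mask_factor[r] * rows$bias[r]
      relu[r] <- u0
    }
  }
  tibble::tibble(
    jurisdiction_id = id,
    mask_variant = rows$mask_variant, source = rows$source,
    pool = rows$pool, type = rows$type,
    density_mg_ha = density, ratio = ratio_col, rel_uncertainty = relu
  )
}

#' Apply the jurisdiction inclusion rules
#'
#' Nations need at least 1,000 km2 of forest (as mapped by the reference
#' variant in its first year) to enter the analysis; nations with more than
#' 10,000 km2 are replaced by their level-1 subnational children; subnational
#' units with less than 10% forest cover by land area are excluded.
#'
#' @param sim A `defor_sim`.
#' @param reference_variant Variant whose first-year forest area drives the
#'   screening (default `"modis"`).
#' @return A filtered `defor_sim`; the decision log is attached as attribute
#'   `"screening"`.
#' @export
screen_jurisdictions <- function(sim, reference_variant = "modis") {
  v <- sim$config$variants
  if (!reference_variant %in% v$variant) abort_data("reference variant not present")
  ref_year <- v$first_year[v$variant == reference_variant]
  jur <- sim$jurisdictions
  if (any(is.na(jur$land_area_km2))) abort_data("land_area_km2 missing for some jurisdictions")
  ref_forest <- sim$panels |>
    dplyr::filter(.data$variant == reference_variant, .data$year == ref_year) |>
    dplyr::select("jurisdiction_id", ref_forest_km2 = "forest_km2")
  jur <- dplyr::left_join(jur, ref_forest, by = "jurisdiction_id")

  nat <- dplyr::filter(jur, .data$admin_level == "national")
  log_rows <- list()
  keep <- character(0)
  for (i in seq_len(nrow(nat))) {
    id <- nat$jurisdiction_id[i]
    f <- nat$ref_forest_km2[i]
    kids <- dplyr::filter(jur, !is.na(.data$parent_id) & .data$parent_id == id)
    if (is.na(f) || f < 1000) {
      log_rows[[id]] <- tibble::tibble(jurisdiction_id = id, decision = "excluded",
                                       reason = "forest < 1000 km2")
    } else if (f > 10000) {
      ok <- kids$ref_forest_km2 / kids$land_area_km2 >= 0.10
      keep <- c(keep, kids$jurisdiction_id[ok])
      log_rows[[id]] <- dplyr::bind_rows(
        tibble::tibble(jurisdiction_id = id, decision = "split",
                       reason = "forest > 10,000 km2: replaced by subnational units"),
        tibble::tibble(jurisdiction_id = kids$jurisdiction_id,
                       decision = ifelse(ok, "retained", "excluded"),
                       reason = ifelse(ok, "subnational unit",
                                       "forest cover < 10% of land area")))
    } else {
      keep <- c(keep, id)
      log_rows[[id]] <- tibble::tibble(jurisdiction_id = id, decision = "retained",
                                       reason = "national unit")
    }
  }
  out <- sim
  out$jurisdictions <- dplyr::filter(sim$jurisdictions, .data$jurisdiction_id %in% keep)
  out$panels <- dplyr::filter(sim$panels, .data$jurisdiction_id %in% keep)
  out$drivers <- dplyr::filter(sim$drivers, .data$jurisdiction_id %in% keep)
  out$ground_truth$latent <- dplyr::filter(sim$ground_truth$latent,
                                           .data$jurisdiction_id %in% keep)
  out$ground_truth$jurisdiction_truth <- dplyr::filter(
    sim$ground_truth$jurisdiction_truth, .data$jurisdiction_id %in% keep)
  attr(out, "screening") <- dplyr::bind_rows(log_rows)
  out
}
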
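#' Names of the twelve driver covariates
#'
#' Biophysical and socioeconomic covariates used by the driver-based
#' projection models: terrain (elevation, slope), climate (long-term mean
#' temperature and precipitation), economy (per-capita GDP, human development
#' index, nightlight intensity), demography (population density) and land use
#' (percent forest, agriculture, mining, tree plantations). Synthetic panels
#' carry standardised (unitless) values with these semantics.
#'
#' @return Character vector of length 12.
#' @export
driver_names <- function() {
  c("elevation", "slope", "temperature", "precipitation",
    "gdp", "hdi", "nightlights", "pop_density",
    "pct_forest", "pct_agriculture", "pct_mining", "pct_plantations")
}

#' Region labels used for regional stratification
#' @return Character vector of the six world regions.
#' @export
region_labels <- function() {
  c("Africa", "Asia", "Oceania", "Latin America", "North America", "Europe")
}

# default forest-dataset variant table: three tree-cover-threshold variants of
# one 30 m product sharing a 2000-2021 span, plus two coarser land-cover
# products with their own spans. obs_cv = lognormal observation noise CV on
# annual loss, bias = multiplicative detection bias, forest_scale = fraction of
# the latent forest extent the variant maps, carbon_mask_factor = how the
# variant's forest mask shifts mean carbon density.
default_variants <- function() {
  tibble::tibble(
    variant = c("hansen15", "hansen30", "hansen60", "modis", "esacci"),
    first_year = c(2000L, 2000L, 2000L, 2001L, 1992L),
    last_year = c(2021L, 2021L, 2021L, 2020L, 2020L),
    obs_cv = c(0.10, 0.10, 0.10, 0.15, 0.20),
    bias = c(1.15, 1.00, 0.85, 0.90, 1.10),
    forest_scale = c(1.00, 0.90, 0.70, 0.80, 1.05),
    carbon_mask_factor = c(0.95, 1.00, 1.10, 1.00, 0.90)
  )
}

# default carbon source table. type "sparse" emulates a lidar-track product
# that samples a fraction of a jurisdiction's area; type "ratio" derives
# belowground biomass as a region-specific root:shoot ratio of the chosen
# aboveground source. rel_uncertainty NA means no provider value is available
# and the 33% default applies (see default_uncertainty()).
default_carbon_sources <- function() {
  tibble::tibble(
    source = c("spawn_agb", "gedi_agb", "soto_agb",
               "spawn_bgb", "soto_bgb", "ipcc_bgb",
               "esdac_soc", "olm_soc"),
    pool = c("agb", "agb", "agb", "bgb", "bgb", "bgb", "soc", "soc"),
    type = c("dense", "sparse", "dense", "dense", "dense", "ratio",
             "dense", "dense"),
    bias = c(1.00, 1.05, 0.95, 1.00, 0.95, NA, 1.00, 1.05),
    rel_uncertainty = c(0.15, 0.20, NA, 0.20, NA, NA, NA, 0.25)
  )
}

# region-specific root:shoot ratios used by the ratio-type BGB source
# (synthetic values in the range of published defaults)
default_bgb_ratios <- function() {
  tibble::tibble(
    region = region_labels(),
    ratio = c(0.24, 0.26, 0.25, 0.24, 0.29, 0.29)
  )
}

#' Configuration for the synthetic jurisdiction generator
#'
#' Defines the study conditions the generator emulates: a latent
#' driver-driven deforestation process per jurisdiction observed by five
#' noisy, biased forest-dataset variants; twelve driver covariates of which a
#' few have true nonzero effect; and multi-source carbon densities including
#' one sparsely sampled source. All defaults are documented in the package
#' vignette.
#'
#' @param n_jurisdictions Number of national jurisdictions to generate.
#' @param seed Integer root seed; every draw derives from it via named
#'   streams (see [stream_seed()]).
#' @param variants Tibble of dataset variants (columns `variant`,
#'   `first_year`, `last_year`, `obs_cv`, `bias`, `forest_scale`,
#'   `carbon_mask_factor`). Spans must cover at least 16 years so the longest
#'   15-year reference window fits.
#' @param driver_effects Named numeric vector of true per-driver coefficients
#'   on the log latent deforestation rate; names must be a subset of
#'   [driver_names()]. Unnamed drivers have zero effect.
#' @param ar1_coefficient AR(1) coefficient of the latent log-rate noise, in
#'   `[0, 1)`.
#' @param ar1_sd Stationary (marginal) standard deviation of the AR(1) noise
#'   on the log scale.
#' @param base_rate_fraction Expected annual deforestation as a fraction of
#'   initial forest area (log-scale intercept is
#'   `log(base_rate_fraction * forest0)`).
#' @param forest_area_mean_km2,forest_area_sdlog Lognormal parameters of
#'   initial national forest area.
#' @param n_children Number of subnational (level-1) children generated per
#'   national jurisdiction; children partition the national latent series by
#'   a seeded Dirichlet share vector.
#' @param dirichlet_alpha Concentration of the Dirichlet share vector.
#' @param carbon_sources Tibble of carbon sources (see package vignette).
#' @param bgb_ratios Tibble mapping region to root:shoot ratio for the
#'   ratio-type BGB source.
#' @param agb_mean,agb_sdlog,soc_mean,soc_sdlog Lognormal parameters of true
#'   jurisdiction mean AGB biomass and SOC carbon densities (Mg/ha).
#' @param sparse_sampling_fraction Fraction of a jurisdiction's sub-units the
#'   sparse carbon source observes, in `(0, 1]`.
#' @param n_cells Number of equal-area sub-units per jurisdiction used by the
#'   sparse source.
#' @param cell_cv Coefficient of variation of sub-unit carbon densities
#'   around the jurisdiction mean.
#' @param area_noise_exponent If nonzero, observation noise CVs are scaled by
#'   `(forest0 / forest_area_mean_km2)^(-area_noise_exponent)`; 0.5 makes
#'   noise scale as one over the square root of forest area (small
#'   jurisdictions noisier, as for pixel-counting estimators).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_jurisdictions = 20,
                             seed = 1L,
                             variants = default_variants(),
                             driver_effects = c(gdp = 0.40, pop_density = 0.30,
                                                slope = -0.25, pct_agriculture = 0.20),
                             ar1_coefficient = 0.4,
                             ar1_sd = 0.15,
                             base_rate_fraction = 0.005,
                             forest_area_mean_km2 = 5000,
                             forest_area_sdlog = 0.8,
                             n_children = 4,
                             dirichlet_alpha = 2,
                             carbon_sources = default_carbon_sources(),
                             bgb_ratios = default_bgb_ratios(),
                             agb_mean = 150, agb_sdlog = 0.4,
                             soc_mean = 80, soc_sdlog = 0.3,
                             sparse_sampling_fraction = 0.05,
                             n_cells = 1000,
                             cell_cv = 0.3,
                             area_noise_exponent = 0) {
  cfg <- list(
    n_jurisdictions = as.integer(n_jurisdictions), seed = as.integer(seed),
    variants = variants, driver_effects = driver_effects,
    ar1_coefficient = ar1_coefficient, ar1_sd = ar1_sd,
    base_rate_fraction = base_rate_fraction,
    forest_area_mean_km2 = forest_area_mean_km2,
    forest_area_sdlog = forest_area_sdlog,
    n_children = as.integer(n_children), dirichlet_alpha = dirichlet_alpha,
    carbon_sources = carbon_sources, bgb_ratios = bgb_ratios,
    agb_mean = agb_mean, agb_sdlog = agb_sdlog,
    soc_mean = soc_mean, soc_sdlog = soc_sdlog,
    sparse_sampling_fraction = sparse_sampling_fraction,
    n_cells = as.integer(n_cells), cell_cv = cell_cv,
    area_noise_exponent = area_noise_exponent
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  v <- cfg$variants
  spans <- v$last_year - v$first_year + 1L
  if (any(spans < 16L)) {
    abort_config("every dataset variant span must cover at least 16 years (15-year reference window + 1)")
  }
  if (any(v$obs_cv < 0)) abort_config("observation noise CVs must be >= 0")
  if (any(v$bias <= 0) || any(v$forest_scale <= 0)) {
    abort_config("dataset bias and forest-scale factors must be > 0")
  }
  if (!all(names(cfg$driver_effects) %in% driver_names())) {
    abort_config("driver_effects names must be among driver_names()")
  }
  if (any(!is.finite(cfg$driver_effects))) abort_config("driver effect sizes must be finite")
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1) {
    abort_config("ar1_coefficient must lie in [0, 1)")
  }
  if (cfg$sparse_sampling_fraction <= 0 || cfg$sparse_sampling_fraction > 1) {
    abort_config("sparse_sampling_fraction must lie in (0, 1]")
  }
  if (cfg$n_jurisdictions < 1) abort_config("n_jurisdictions must be >= 1")
  invisible(cfg)
}

#' Configuration of the method grid
#'
#' Describes which levels of each method parameter the grid engine crosses.
#' The full published grid (seven projection approaches, five forest
#' datasets, reference lengths 5--15 years, every admissible start year, five
#' carbon forest masks, three AGB sources, three BGB sources, two SOC
#' sources) is expressible; the defaults thin the reference lengths and start
#' years to desk scale.
#'
#' @param approaches Projection approaches, subset of
#'   `c("hist","linear","poly2","global","global_s","regional","regional_s")`.
#' @param defor_variants Forest-dataset variants used for deforestation.
#' @param ref_lengths Historical reference period lengths in years (5--15).
#' @param n_start_years Number of admissible start years retained per
#'   (variant, length), evenly spaced over the admissible range; `NULL` keeps
#'   all of them.
#' @param carbon_mask_variants Forest-dataset variants used as carbon masks.
#' @param agb_sources,bgb_sources,soc_sources Carbon source identifiers.
#' @param ensemble_reps Number of random-subset members per ensemble model.
#' @param ensemble_size_range Inclusive range of driver-subset sizes drawn
#'   per ensemble member.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(approaches = c("hist", "linear", "poly2",
                                       "global", "global_s",
                                       "regional", "regional_s"),
                        defor_variants = default_variants()$variant,
                        ref_lengths = c(5L, 10L, 15L),
                        n_start_years = 2L,
                        carbon_mask_variants = default_variants()$variant,
                        agb_sources = c("spawn_agb", "gedi_agb", "soto_agb"),
                        bgb_sources = c("spawn_bgb", "soto_bgb", "ipcc_bgb"),
                        soc_sources = c("esdac_soc", "olm_soc"),
                        ensemble_reps = 300L,
                        ensemble_size_range = c(3L, 11L)) {
  known <- c("hist", "linear", "poly2", "global", "global_s", "regional", "regional_s")
  if (!all(approaches %in% known)) abort_config("unknown projection approach")
  if (any(ref_lengths < 5L) || any(ref_lengths > 15L)) {
    abort_config("reference lengths must lie in 5..15 years")
  }
  if (!length(approaches) || !length(defor_variants) || !length(ref_lengths) ||
      !length(carbon_mask_variants) || !length(agb_sources) ||
      !length(bgb_sources) || !length(soc_sources)) {
    abort_config("every grid dimension needs at least one level")
  }
  structure(list(
    approaches = approaches, defor_variants = defor_variants,
    ref_lengths = as.integer(ref_lengths),
    n_start_years = if (is.null(n_start_years)) NULL else as.integer(n_start_years),
    carbon_mask_variants = carbon_mask_variants,
    agb_sources = agb_sources, bgb_sources = bgb_sources,
    soc_sources = soc_sources,
    ensemble_reps = as.integer(ensemble_reps),
    ensemble_size_range = as.integer(ensemble_size_range)
  ), class = "grid_config")
}
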
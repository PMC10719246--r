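pipeline_stages <- function() {
  c("simulate", "project", "carbon", "grid", "metrics", "importance", "report")
}

stage_outputs <- list(
  simulate = c("jurisdictions.csv", "panels.csv", "drivers.csv",
               "ground_truth.csv", "ground_truth_coefficients.csv"),
  project = "projections.csv",
  carbon = c("carbon_sources.csv", "carbon_estimates.csv"),
  grid = "baselines.csv",
  metrics = c("variability.csv", "forecast_errors.csv",
              "uncertainty_summary.csv", "level_tests.csv",
              "tukey_pairs.csv", "area_cv_correlation.csv"),
  importance = "importance.csv",
  report = "report.md"
)

stage_inputs <- list(
  simulate = character(0),
  project = c("jurisdictions.csv", "panels.csv", "drivers.csv"),
  carbon = c("jurisdictions.csv", "panels.csv"),
  grid = c("projections.csv", "carbon_estimates.csv"),
  metrics = c("baselines.csv", "jurisdictions.csv", "panels.csv", "drivers.csv"),
  importance = "baselines.csv",
  report = c("variability.csv", "uncertainty_summary.csv")
)

# resolve a pipeline configuration: path to a YAML file or a list
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_data(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  gen_args <- config$generator %||% list()
  grid_args <- config$grid %||% list()
  grid_args$ref_lengths <- as.integer(grid_args$ref_lengths %||% c(5L, 10L, 15L))
  list(
    seed = as.integer(config$seed %||% 1L),
    generator = gen_args,
    grid = grid_args,
    reference_variant = config$screening$reference_variant %||% "modis",
    uncertainty_threshold = config$metrics$uncertainty_threshold %||% 15,
    importance = config$importance %||% list()
  )
}

build_generator_config <- function(cfg, seed) {
  do.call(generator_config, c(list(seed = seed), cfg$generator))
}

build_grid_config <- function(cfg) {
  do.call(grid_config, cfg$grid)
}

log_stage <- function(stage, seed, msg) {
  message(sprintf("[%s] stage=%s seed=%d %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed, msg))
}

read_out <- function(out_dir, file) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    abort_data(sprintf("missing dependency '%s'; run the producing stage first", file))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# rebuild the sim object from stage outputs (retained units only)
reload_sim <- function(out_dir, gen_cfg) {
  jur <- read_out(out_dir, "jurisdictions.csv")
  keep <- jur$jurisdiction_id[jur$retained]
  list(
    jurisdictions = dplyr::filter(jur, .data$retained) |>
      dplyr::select(-"retained", -"decision"),
    panels = dplyr::filter(read_out(out_dir, "panels.csv"),
                           .data$jurisdiction_id %in% keep),
    drivers = dplyr::filter(read_out(out_dir, "drivers.csv"),
                            .data$jurisdiction_id %in% keep),
    config = gen_cfg
  )
}

#' Run the baseline sensitivity pipeline end to end
#'
#' Executes the requested stages in dependency order -- simulate, project,
#' carbon, grid, metrics, importance, report -- writing each stage's CSV
#' outputs into `out_dir` and a manifest (`run_manifest.json`) with file
#' checksums and row counts. Stages not requested must already have their
#' outputs present in `out_dir`. One root seed drives every random stream,
#' so identical (config, seed) reruns reproduce every output byte.
#'
#' @param config Path to a YAML configuration file or an equivalent list;
#'   see the packaged example
#'   `system.file("extdata", "config-small.yml", package = "deforbase")`.
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run (default all).
#' @param seed Root seed; overrides the config's `seed` entry.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages(), seed = NULL) {
  if (!all(stages %in% pipeline_stages())) {
    abort_config(sprintf("unknown stage(s): %s",
                         paste(setdiff(stages, pipeline_stages()), collapse = ", ")))
  }
  cfg <- resolve_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  gen_cfg <- build_generator_config(cfg, seed)
  gcfg <- build_grid_config(cfg)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  prior <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    NULL
  }
  manifest <- list(seed = seed,
                   config_digest = digest_object(cfg),
                   stages = prior$stages %||% list())
  recorded_md5 <- function(file) {
    for (s in manifest$stages) {
      if (!is.null(s$files[[file]])) return(s$files[[file]])
    }
    NULL
  }

  for (stage in stages) {
    for (f in stage_inputs[[stage]]) {
      read_out(out_dir, f)  # dependency check
      # inputs produced by a skipped stage must match their recorded checksum
      want <- recorded_md5(f)
      if (!is.null(want) &&
          !identical(unname(tools::md5sum(file.path(out_dir, f))), want)) {
        abort_data(sprintf(
          "stale checksum for '%s': file differs from the manifest; rerun its producing stage",
          f))
      }
    }
    log_stage(stage, seed, "start")
    rows <- switch(
      stage,
      simulate = stage_simulate(cfg, gen_cfg, out_dir),
      project = stage_project(cfg, gen_cfg, gcfg, out_dir, seed),
      carbon = stage_carbon(cfg, gen_cfg, out_dir, gcfg),
      grid = stage_grid(out_dir),
      metrics = stage_metrics(cfg, gen_cfg, gcfg, out_dir, seed),
      importance = stage_importance(cfg, out_dir, seed),
      report = { render_report(out_dir); 1L }
    )
    files <- stage_outputs[[stage]]
    manifest$stages[[stage]] <- list(
      rows = rows,
      completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      files = as.list(tools::md5sum(file.path(out_dir, files)) |>
                        stats::setNames(files))
    )
    log_stage(stage, seed, sprintf("done rows=%d", rows))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

write_out <- function(x, out_dir, file) {
  readr::write_csv(x, file.path(out_dir, file), progress = FALSE)
  nrow(x)
}

stage_simulate <- function(cfg, gen_cfg, out_dir) {
  sim <- generate_panels(gen_cfg)
  screened <- screen_jurisdictions(sim, cfg$reference_variant)
  jur <- sim$jurisdictions |>
    dplyr::mutate(retained = .data$jurisdiction_id %in%
                    screened$jurisdictions$jurisdiction_id) |>
    dplyr::left_join(attr(screened, "screening") |>
                       dplyr::distinct(.data$jurisdiction_id, .keep_all = TRUE) |>
                       dplyr::select("jurisdiction_id", "decision"),
                     by = "jurisdiction_id")
  write_out(jur, out_dir, "jurisdictions.csv")
  write_out(sim$drivers, out_dir, "drivers.csv")
  write_out(sim$ground_truth$latent, out_dir, "ground_truth.csv")
  write_out(sim$ground_truth$coefficients, out_dir, "ground_truth_coefficients.csv")
  write_out(sim$panels, out_dir, "panels.csv")
}

stage_project <- function(cfg, gen_cfg, gcfg, out_dir, seed) {
  sim <- reload_sim(out_dir, gen_cfg)
  proj <- run_projections(sim, gcfg, seed = seed)
  write_out(proj, out_dir, "projections.csv")
}

stage_carbon <- function(cfg, gen_cfg, out_dir, gcfg) {
  sim <- reload_sim(out_dir, gen_cfg)
  layers <- generate_carbon_layers(gen_cfg, sim)
  write_out(layers, out_dir, "carbon_sources.csv")
  carbon_grid <- tidyr::expand_grid(
    carbon_mask_variant = gcfg$carbon_mask_variants,
    agb_source = gcfg$agb_sources,
    bgb_source = gcfg$bgb_sources,
    soc_source = gcfg$soc_sources)
  write_out(estimate_carbon(layers, carbon_grid), out_dir, "carbon_estimates.csv")
}

stage_grid <- function(out_dir) {
  proj <- read_out(out_dir, "projections.csv")
  carb <- read_out(out_dir, "carbon_estimates.csv")
  write_out(compute_baseline(proj, carb), out_dir, "baselines.csv")
}

stage_metrics <- function(cfg, gen_cfg, gcfg, out_dir, seed) {
  bl <- read_out(out_dir, "baselines.csv")
  ov <- overall_variability(bl) |>
    dplyr::mutate(parameter = "overall", level = "overall")
  params <- c("approach", "defor_variant", "ref_length", "carbon_mask_variant",
              "agb_source", "bgb_source", "soc_source")
  per <- purrr::map_dfr(params, function(p) per_level_variability(bl, p))
  variability <- dplyr::bind_rows(ov, per)
  write_out(variability, out_dir, "variability.csv")

  tests <- purrr::map(params, function(p) {
    dat <- dplyr::filter(per, .data$parameter == p, !is.na(.data$cv_percent))
    if (length(unique(dat$level)) < 2L) return(NULL)
    cmp <- compare_levels(dat)
    list(anova = dplyr::mutate(cmp$anova, parameter = p, .before = 1),
         tukey = dplyr::mutate(cmp$tukey, parameter = p, .before = 1))
  })
  tests <- purrr::compact(tests)
  write_out(purrr::map_dfr(tests, "anova"), out_dir, "level_tests.csv")
  write_out(purrr::map_dfr(tests, "tukey"), out_dir, "tukey_pairs.csv")

  write_out(uncertainty_summaries(bl, cfg$uncertainty_threshold),
            out_dir, "uncertainty_summary.csv")

  sim <- reload_sim(out_dir, gen_cfg)
  fe <- hindcast_grid(sim, gcfg, seed = stream_seed(seed, "hindcast"))
  write_out(fe, out_dir, "forecast_errors.csv")

  ref_year <- gen_cfg$variants$first_year[
    gen_cfg$variants$variant == cfg$reference_variant]
  areas <- sim$panels |>
    dplyr::filter(.data$variant == cfg$reference_variant,
                  .data$year == ref_year) |>
    dplyr::select("jurisdiction_id", forest_km2 = "forest_km2")
  corr_dat <- dplyr::inner_join(ov, areas, by = "jurisdiction_id")
  corr <- tryCatch(area_variability_correlation(corr_dat),
                   error = function(e) tibble::tibble(
                     pearson_r = NA_real_, p_value = NA_real_, n = nrow(corr_dat)))
  write_out(corr, out_dir, "area_cv_correlation.csv")
}

stage_importance <- function(cfg, out_dir, seed) {
  bl <- read_out(out_dir, "baselines.csv")
  args <- cfg$importance
  imp <- variable_importance(
    bl,
    include_start_year = isTRUE(args$include_start_year),
    n_models = args$n_models %||% 20,
    n_trees = args$n_trees %||% 50,
    sample_rows = args$sample_rows %||% 50000,
    seed = stream_seed(seed, "importance"))
  write_out(tibble::as_tibble(imp), out_dir, "importance.csv")
}

fmt_range <- function(x, suffix = "", probs = c(0.05, 0.95)) {
  q <- stats::quantile(x, probs, na.rm = TRUE, names = FALSE)
  sprintf("%.1f%s (90%% range: %.1f%s-%.1f%s)", stats::median(x, na.rm = TRUE),
          suffix, q[1], suffix, q[2], suffix)
}

#' Render a markdown summary report from pipeline outputs
#'
#' Summarises the computed baseline spread (median and 90% range of the
#' overall CV), the per-parameter level comparisons with ANOVA and Tukey
#' results, hindcast forecast errors, uncertainty medians with
#' threshold-exceedance fractions, and the variable-importance ranking.
#' Sections whose inputs are absent are flagged rather than failing.
#'
#' @param out_dir Directory holding the pipeline's CSV outputs.
#' @return The markdown text, invisibly; also written to
#'   `<out_dir>/report.md`.
#' @export
render_report <- function(out_dir) {
  maybe <- function(file) {
    path <- file.path(out_dir, file)
    if (file.exists(path)) readr::read_csv(path, show_col_types = FALSE) else NULL
  }
  lines <- c("# Deforestation emission baseline sensitivity report", "")

  vb <- maybe("variability.csv")
  lines <- c(lines, "## Relative variability of baselines", "")
  if (is.null(vb)) {
    lines <- c(lines, "_Section not available: variability.csv missing._", "")
  } else {
    ov <- dplyr::filter(vb, .data$parameter == "overall")
    lines <- c(lines, sprintf(
      "Median jurisdiction CV across all methods: %s over %d jurisdictions.",
      fmt_range(ov$cv_percent, "%"), nrow(ov)), "")
    lt <- maybe("level_tests.csv")
    if (!is.null(lt) && nrow(lt)) {
      lines <- c(lines, "Per-parameter one-way ANOVA on per-level CVs:", "",
                 "| parameter | F | df | p |", "|---|---|---|---|",
                 sprintf("| %s | %.3g | (%d, %d) | %.3g |",
                         lt$parameter, lt$statistic, lt$df_between,
                         lt$df_within, lt$p_value), "")
      tk <- maybe("tukey_pairs.csv")
      if (!is.null(tk) && nrow(tk)) {
        sig <- dplyr::count(dplyr::filter(tk, .data$adj_p_value < 0.05),
                            .data$parameter)
        tot <- dplyr::count(tk, .data$parameter, name = "total")
        sg <- dplyr::left_join(tot, sig, by = "parameter")
        lines <- c(lines, sprintf("- %s: %d of %d Tukey pairs significant at 0.05",
                                  sg$parameter,
                                  dplyr::coalesce(sg$n, 0L), sg$total), "")
      }
    }
  }

  fe <- maybe("forecast_errors.csv")
  lines <- c(lines, "## Hindcast forecast error", "")
  if (is.null(fe) || !nrow(fe)) {
    lines <- c(lines, "_Section not available: forecast_errors.csv missing or empty._", "")
  } else {
    med_jur <- fe |>
      dplyr::filter(!is.na(.data$forecast_error)) |>
      dplyr::group_by(.data$jurisdiction_id) |>
      dplyr::summarise(med = stats::median(.data$forecast_error), .groups = "drop")
    q <- stats::quantile(med_jur$med, c(0.05, 0.95), names = FALSE)
    lines <- c(lines, sprintf(
      "Median jurisdiction's median |predicted-actual|/actual: %.3f (90%% range: %.3f-%.3f).",
      stats::median(med_jur$med), q[1], q[2]), "",
      "Median forecast error by approach:", "")
    by_app <- fe |>
      dplyr::filter(!is.na(.data$forecast_error)) |>
      dplyr::group_by(.data$approach) |>
      dplyr::summarise(med = stats::median(.data$forecast_error), .groups = "drop")
    lines <- c(lines, sprintf("- %s: %.3f", by_app$approach, by_app$med), "")
  }

  us <- maybe("uncertainty_summary.csv")
  lines <- c(lines, "## Propagated uncertainty", "")
  if (is.null(us)) {
    lines <- c(lines, "_Section not available: uncertainty_summary.csv missing._", "")
  } else {
    agg <- us |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(med = stats::median(.data$median_rel_uncertainty_pct),
                       frac = stats::median(.data$fraction_exceeding),
                       .groups = "drop")
    lines <- c(lines, sprintf(
      "- %s: median %.1f%% relative uncertainty; median fraction of methods over %g%%: %.2f",
      agg$component, agg$med, us$threshold_pct[1], agg$frac), "")
  }

  imp <- maybe("importance.csv")
  lines <- c(lines, "## Variable importance of grid parameters", "")
  if (is.null(imp)) {
    lines <- c(lines, "_Section not available: importance stage not run._", "")
  } else {
    lines <- c(lines, "| rank | parameter | mean | SE |", "|---|---|---|---|",
               sprintf("| %d | %s | %.3g | %.3g |", imp$rank, imp$parameter,
                       imp$importance_mean, imp$importance_se), "")
  }

  corr <- maybe("area_cv_correlation.csv")
  lines <- c(lines, "## Forest area and variability", "")
  if (is.null(corr) || is.na(corr$pearson_r[1])) {
    lines <- c(lines, "_Section not available._", "")
  } else {
    lines <- c(lines, sprintf(
      "Pearson r between log forest area and overall CV: %.3f (p = %.3g, n = %d).",
      corr$pearson_r[1], corr$p_value[1], corr$n[1]), "")
  }

  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(paste(lines, collapse = "\n"))
}
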
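#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis with the
#' study defaults: 50 pseudo-absences per presence, fence barrier
#' resistance 100, top-10% corridor threshold, corridor widths
#' 0.5/1/2/3 km, and US$75 per acre removal cost. All values can be
#' overridden; the realized config is echoed into the run manifest.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    grid_shape = c(100, 100), cell_size = 500, seed = 1,
    n_animals = 6, n_steps = 300,
    step_mean = 11, step_sd = 9, fix_interval = 3,
    validation_fix_interval = 4, n_validation_animals = 5,
    n_validation_steps = 200,
    pseudo_ratio = 50, barrier_value = 100, top_fraction = 0.10,
    widths_km = c(0.5, 1, 2, 3), unit_cost_per_acre = 75,
    covariates = NULL, r_min = 1, r_max = 100,
    rsf_method = "glmm", evaluate_scenarios = TRUE, include_fences = TRUE,
    validation_start = "west")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full fence-removal prioritization pipeline
#'
#' End-to-end driver on the synthetic study system: simulate landscape and
#' movement, fit the selection model, predict suitability, build
#' pre-fencing and fenced resistance surfaces, solve pre-fencing and fenced
#' connectivity, map the connectivity change, evaluate every fence-removal
#' scenario, and validate all modeled surfaces with an independent
#' (4-h interval) validation trajectory set simulated under the fenced
#' landscape. Outputs and a manifest (inputs, hashes, seeds, versions) are
#' written to `out_dir`; partial outputs are retained on stage failure.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` for no
#'   file output.
#' @return List with all stage products: `world`, `rsf`, `suitability`,
#'   `resistance`, `resistance_fenced`, `cm_pre`, `cm_fenced`, `change`,
#'   `corridor_mask`, `scenarios`, `validation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_raster <- function(r, name) {
    if (!is.null(out_dir)) write_raster_ascii(r, file.path(out_dir, paste0(name, ".asc")))
  }

  world <- run_stage("simulate", simulate_fenced_world(
    config$seed, config$grid_shape, config$cell_size))
  if (!isTRUE(config$include_fences)) {
    world$fences <- fence_network()
    world$parcels <- list()
  }
  covs <- if (is.null(config$covariates)) world$covariates else config$covariates

  traj <- run_stage("simulate", simulate_trajectories(
    world$stack, world$true_beta, n_animals = config$n_animals,
    n_steps = config$n_steps, step_mean = config$step_mean,
    step_sd = config$step_sd, fix_interval = config$fix_interval,
    fences = NULL, covariates = covs, seed = config$seed + 1L))

  pa <- run_stage("fit", sample_pseudo_absences(
    traj, world$stack, pseudo_ratio = config$pseudo_ratio,
    seed = config$seed + 2L))
  rsf <- run_stage("fit", fit_rsf(pa, covariates = covs,
                                  method = config$rsf_method))

  suit <- run_stage("predict", predict_suitability(rsf, world$stack))
  emit_raster(suit, "suitability")

  r_pre <- run_stage("resistance", suitability_to_resistance(
    suit, config$r_min, config$r_max))
  r_fen <- run_stage("resistance", burn_fences(
    r_pre, world$fences, config$barrier_value, parcels = world$parcels))
  emit_raster(r_pre, "resistance_prefence")
  emit_raster(r_fen, "resistance_fenced")

  cm_pre <- run_stage("connect", cumulative_current(
    build_graph(r_pre, world$focal)))
  cm_fen <- run_stage("connect", cumulative_current(
    build_graph(r_fen, world$focal)))
  emit_raster(cm_pre$cumulative, "current_prefence")
  emit_raster(cm_fen$cumulative, "current_fenced")

  change <- run_stage("change-map", connectivity_change(cm_fen, cm_pre))
  corridor_mask <- run_stage("change-map", identify_corridors(
    cm_pre, config$top_fraction))
  emit_raster(change, "current_change")
  emit_raster(corridor_mask$mask, "corridor_mask")

  scenarios <- if (isTRUE(config$evaluate_scenarios)) {
    run_stage("scenarios", run_scenarios(
      r_pre, world$fences, world$corridors, world$focal,
      widths_km = config$widths_km,
      unit_cost_per_acre = config$unit_cost_per_acre,
      barrier_value = config$barrier_value, parcels = world$parcels))
  } else NULL

  # validation collars are deployed in a named seasonal range (default the
  # western range), mirroring the study design; NULL means random starts
  vstart <- NULL
  if (!is.null(config$validation_start)) {
    reg <- Filter(function(f) f$name == config$validation_start, world$focal)
    if (length(reg)) {
      poly <- reg[[1]]$polygon
      vstart <- withr::with_seed(config$seed + 5L, cbind(
        stats::runif(config$n_validation_animals, min(poly[, 1]), max(poly[, 1])),
        stats::runif(config$n_validation_animals, min(poly[, 2]), max(poly[, 2]))))
    }
  }
  vtraj <- run_stage("validate", simulate_trajectories(
    world$stack, world$true_beta, n_animals = config$n_validation_animals,
    n_steps = config$n_validation_steps, step_mean = config$step_mean,
    step_sd = config$step_sd, fix_interval = config$validation_fix_interval,
    fences = world$fences, covariates = covs, start_xy = vstart,
    seed = config$seed + 3L))
  vpa <- run_stage("validate", sample_pseudo_absences(
    vtraj, world$stack, pseudo_ratio = config$pseudo_ratio,
    seed = config$seed + 4L))
  validation <- run_stage("validate", validate_surfaces(
    vpa, list(suitability = suit, prefence_current = cm_pre$cumulative,
              fenced_current = cm_fen$cumulative, change = change),
    roi = world$roi))

  if (!is.null(out_dir)) {
    if (!is.null(scenarios)) {
      readr::write_csv(scenarios, file.path(out_dir, "scenario_results.csv"))
    }
    readr::write_csv(validation, file.path(out_dir, "validation_results.csv"))
    write_trajectories_csv(traj, file.path(out_dir, "trajectories.csv"))
    write_fences_geojson(world$fences, file.path(out_dir, "fences.geojson"))
    write_regions_geojson(world$focal, file.path(out_dir, "focal_regions.geojson"))
    write_parcels_geojson(world$parcels, file.path(out_dir, "parcels.geojson"))
  }

  manifest <- list(
    package = "fenceflow",
    version = as.character(utils::packageVersion("fenceflow")),
    config = unclass(config),
    rsf_method = rsf$fit_meta$method,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = if (!is.null(out_dir)) {
      fls <- list.files(out_dir, full.names = TRUE)
      fls <- fls[basename(fls) != "manifest.json"]
      stats::setNames(as.vector(tools::md5sum(fls)), basename(fls))
    } else list())
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(world = world, trajectories = traj, rsf = rsf, suitability = suit,
       resistance = r_pre, resistance_fenced = r_fen, cm_pre = cm_pre,
       cm_fenced = cm_fen, change = change, corridor_mask = corridor_mask,
       scenarios = scenarios, validation = validation, manifest = manifest)
}
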
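#' Default pipeline configuration
#'
#' Every numeric parameter of the downstream stages appears here as a named
#' key whose default is the published value where one exists (SDR
#' calibration IC0 = 0.5, k = 2.0, max SDR = 0.8; 3 km plume cutoff;
#' alpha = 0.10; ten-fold CV; >90% linkage; >66% export prioritization;
#' 100 m buffers; depth limit 22 m; 163 surveys). Values may be overridden
#' by a YAML file (see [read_pipeline_config]).
#'
#' @param ... named overrides merged (recursively) over the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    scenario = "current",          # current | deforestation | restoration
    bleaching = "none",            # none | low | moderate | high
    bleaching_mode = "proportional",
    synthetic = list(n_cells = 200L, n_valleys = 4L, n_sites = 163L,
                     noise_sd = 1.0),
    paths = NULL,                  # optional input rasters (see read_bundle)
    erosivity_mode = "monthly",
    sdr = list(ic0 = 0.5, k_borselli = 2.0, sdr_max = 0.8,
               flow_accum_threshold = 50, k_fill = 0.002),
    c_factors = as.list(default_c_factors()),
    plume = list(w_depth = 1 / 3, w_dist = 1 / 3, w_wind = 1 / 3,
                 max_distance_m = 3000),
    drivers = list(exposure_window = 3, shannon_window_m = 270,
                   proximity_radius_m = 500),
    brt = list(lr_grid = c(0.01, 0.005, 0.001), tc_grid = c(1, 2, 3, 5),
               bag_grid = c(0.5, 0.75), max_trees = 10000, folds = 10),
    r_max = 0.7,
    max_depth_m = 22,
    alpha = 0.10,
    prioritize = list(link_threshold = 0.90, export_frac = 0.66,
                      buffer_m = 100)
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config].
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

brt_config_from <- function(cfg) {
  brt_config(lr_grid = cfg$brt$lr_grid, tc_grid = cfg$brt$tc_grid,
             bag_grid = cfg$brt$bag_grid, max_trees = cfg$brt$max_trees,
             folds = cfg$brt$folds, seed = cfg$seed)
}

sdr_params_from <- function(cfg) do.call(sdr_params, cfg$sdr)

plume_params_from <- function(cfg) do.call(plume_params, cfg$plume)

BENTHIC_INDICATORS <- c("cca", "coral", "macroalgae", "turf")
FISH_INDICATORS <- c("browsers", "grazers", "scrapers", "predators")

# Predict the 8 indicator maps for one scenario's TSS field, applying the
# bleaching adjustment to the coral map before the fish models consume it.
predict_indicator_maps <- function(hier, stack, tss, spec, depth,
                                   max_depth_m) {
  st <- stack
  st$tss <- tss
  benthic_maps <- lapply(hier$benthic, predict_map, stack = st,
                         max_depth_m = max_depth_m)
  if (spec$bleaching != "none")
    benthic_maps$coral <- apply_bleaching(benthic_maps$coral, depth, spec)
  st2 <- c(st, benthic_maps)
  fish_maps <- lapply(hier$fish, predict_map, stack = st2,
                      max_depth_m = max_depth_m)
  c(benthic_maps, fish_maps)
}

#' Run the linked land-sea pipeline
#'
#' Chains all stages on the synthetic island (or user rasters): land-use
#' scenario construction, sediment export, coastal plume dispersal, marine
#' driver derivation, reef-survey simulation, hierarchical BRT calibration,
#' indicator map prediction under the present and scenario conditions,
#' per-cell significance assessment, and land prioritization. Writes grids
#' (ESRI ASCII), tables (CSV), models (JSON) and a log under `outdir`.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the key in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("r2r_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    say("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  spec <- scenario_spec(config$scenario, config$bleaching,
                        config$bleaching_mode)

  bundle <- stage("synth", {
    if (!is.null(config$paths)) read_bundle(config$paths)
    else make_island(config$seed, config$synthetic$n_cells,
                     config$synthetic$n_valleys)
  })

  cfac <- unlist(config$c_factors)
  sedi <- list(); plume <- list()
  scenarios_needed <- unique(c("current", config$scenario))
  sp_cur <- scenario_spec("current", "none")
  geo <- compute_geography(bundle$bathy, bundle$coastline, "positive_down")
  for (sc in scenarios_needed) {
    lu <- stage("scenario", apply_landuse_scenario(
      bundle$land_cover, bundle$luc, bundle$concessions,
      scenario_spec(sc, "none"), cfac))
    sedi[[sc]] <- stage("sediment", sediment_stage(
      bundle$dem, bundle$rain, bundle$K, lu$C, bundle$pour_points,
      sdr_params_from(config), config$erosivity_mode))
    plume[[sc]] <- stage("plume", plume_stage(
      bundle$bathy, geo$dist_shore, bundle$wind_exposure,
      sedi[[sc]]$result$watershed_loads, bundle$pour_points,
      plume_params_from(config)))
    write_grid(sedi[[sc]]$result$export,
               file.path(outdir, paste0("export_", sc, ".asc")))
    write_grid(plume[[sc]]$tss, file.path(outdir, paste0("tss_", sc, ".asc")))
    write.csv(sedi[[sc]]$result$watershed_loads,
              file.path(outdir, paste0("watershed_loads_", sc, ".csv")),
              row.names = FALSE)
    if (sc != "current")
      write.csv(lu$ledger, file.path(outdir, "scenario_ledger.csv"),
                row.names = FALSE)
  }

  stack <- stage("drivers", do.call(marine_driver_stack, c(
    list(bathy = bundle$bathy, habitat = bundle$habitat,
         coastline = bundle$coastline), config$drivers)))
  pred_stack <- stack[setdiff(names(stack), "aspect")]

  surveys <- stage("surveys", {
    bundle$tss <- plume$current$tss
    make_reef_surveys(bundle, n_sites = config$synthetic$n_sites,
                      noise_sd = config$synthetic$noise_sd,
                      seed = config$seed + 11L)
  })
  write.csv(as.data.frame(surveys), file.path(outdir, "surveys.csv"),
            row.names = FALSE)

  hier <- stage("fit", {
    bcfg <- brt_config_from(config)
    btabs <- lapply(BENTHIC_INDICATORS, function(ind) sample_predictors(
      c(pred_stack, list(tss = plume$current$tss)), surveys, ind, "sqrt"))
    names(btabs) <- BENTHIC_INDICATORS
    ftabs <- lapply(FISH_INDICATORS, function(ind) sample_predictors(
      c(pred_stack, list(tss = plume$current$tss)), surveys, ind,
      "fourth_root", extra_predictors = BENTHIC_INDICATORS))
    names(ftabs) <- FISH_INDICATORS
    fit_hierarchy(btabs, ftabs, bcfg, config$r_max)
  })
  diag <- do.call(rbind, lapply(c(hier$benthic, hier$fish), function(m)
    data.frame(indicator = m$response, transform = m$transform,
               lr = m$best$lr, tc = m$best$tc, bag = m$best$bag,
               n_trees = m$n_trees, pde = m$pde, cv_pde = m$cv_pde)))
  write.csv(diag, file.path(outdir, "model_diagnostics.csv"),
            row.names = FALSE)
  curves <- do.call(rbind, lapply(c(hier$benthic, hier$fish), function(m)
    cbind(indicator = m$response, m$curves)))
  write.csv(curves, file.path(outdir, "response_curves.csv"),
            row.names = FALSE)
  dir.create(file.path(outdir, "models"), showWarnings = FALSE)
  for (m in c(hier$benthic, hier$fish))
    write_brt(m, file.path(outdir, "models",
                           paste0("brt_", m$response, ".json")))

  maps <- stage("predict", {
    present <- predict_indicator_maps(hier, pred_stack, plume$current$tss,
                                      sp_cur, stack$depth, config$max_depth_m)
    scen <- predict_indicator_maps(hier, pred_stack,
                                   plume[[config$scenario]]$tss, spec,
                                   stack$depth, config$max_depth_m)
    list(present = present, scenario = scen)
  })
  for (nm in names(maps$present)) {
    write_grid(maps$present[[nm]],
               file.path(outdir, paste0("map_present_", nm, ".asc")))
    write_grid(maps$scenario[[nm]],
               file.path(outdir, paste0("map_scenario_", nm, ".asc")))
  }

  assess <- stage("assess", {
    sig <- lapply(names(maps$present), function(nm)
      sig_diff(maps$scenario[[nm]], maps$present[[nm]], config$alpha))
    names(sig) <- names(maps$present)
    summary <- summarize_impact(sig, FISH_INDICATORS,
                                cell_area_ha = bundle$bathy$cell_size^2 / 1e4)
    summary$scenario <- config$scenario
    summary$bleaching <- config$bleaching
    write.csv(summary, file.path(outdir, "impact_summary.csv"),
              row.names = FALSE)
    list(sig = sig, summary = summary)
  })

  prior <- stage("prioritize", {
    sig_any <- Reduce(function(a, b) {
      g <- grid_like(a)
      g$values <- pmax(a$values, b$values, na.rm = TRUE)
      g
    }, lapply(assess$sig, function(s) s$significant))
    lw <- tryCatch(
      link_watersheds(sig_any, plume[[config$scenario]]$plumes,
                      config$prioritize$link_threshold),
      error = function(e) list(linked = character(0), contributions = NULL))
    if (length(lw$linked)) {
      mode <- if (config$scenario == "current") "climate" else "landuse"
      mask <- priority_land_areas(
        sedi$current$result$export, sedi$current$watersheds, lw$linked,
        mode = mode, frac = config$prioritize$export_frac,
        export_scenario = sedi[[config$scenario]]$result$export,
        alpha = config$alpha,
        flow_accum = sedi$current$routing$flow_accum)
      pp <- buffer_priority(mask, config$prioritize$buffer_m,
                            clip_to = bundle$dem)
      write_grid(mask, file.path(outdir, "priority_mask.asc"))
      write_priority_geojson(pp, file.path(outdir, "priority_areas.geojson"))
      if (!is.null(lw$contributions))
        write.csv(cbind(scenario = config$scenario, lw$contributions),
                  file.path(outdir, "linkage.csv"), row.names = FALSE)
      list(linked = lw$linked, mask = mask, polygons = pp,
           contributions = lw$contributions)
    } else {
      say("no significant reef change: empty priority set")
      list(linked = character(0), mask = NULL, polygons = NULL,
           contributions = NULL)
    }
  })
  say("done")
  invisible(list(bundle = bundle, sediment = sedi, plume = plume,
                 stack = stack, surveys = surveys, models = hier,
                 maps = maps, assess = assess, prioritize = prior,
                 outdir = outdir))
}

#' Read an input bundle from raster/vector files
#'
#' Loads user-supplied layers in place of the synthetic island. `paths` is
#' a named list: `dem`, `land_cover`, `luc`, `concessions`, `K` (30 m ESRI
#' ASCII), `rain` (vector of 12 monthly paths), `bathy`, `habitat`,
#' `coastline`, `wind_exposure` (60 m), and `pour_points` (CSV with id, x,
#' y).
#'
#' @param paths named list of file paths.
#' @return an `island_bundle`-shaped list.
#' @export
read_bundle <- function(paths) {
  need <- c("dem", "land_cover", "luc", "concessions", "K", "rain", "bathy",
            "habitat", "coastline", "wind_exposure", "pour_points")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  structure(list(
    dem = read_grid(paths$dem),
    land_cover = read_grid(paths$land_cover, method = "nearest"),
    luc = read_grid(paths$luc, method = "nearest"),
    concessions = read_grid(paths$concessions, method = "nearest"),
    K = read_grid(paths$K),
    rain = lapply(paths$rain, read_grid),
    bathy = read_grid(paths$bathy),
    habitat = read_grid(paths$habitat, method = "nearest"),
    coastline = read_grid(paths$coastline, method = "nearest"),
    wind_exposure = read_grid(paths$wind_exposure),
    pour_points = read.csv(paths$pour_points),
    truth = NULL
  ), class = "island_bundle")
}

#' Write a synthetic island bundle to disk
#' @param bundle an `island_bundle`.
#' @param outdir output directory.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gr <- c("dem", "land_cover", "luc", "concessions", "K", "bathy", "habitat",
          "coastline", "wind_exposure", "tss_true")
  for (nm in gr)
    if (!is.null(bundle[[nm]]))
      write_grid(bundle[[nm]], file.path(outdir, paste0(nm, ".asc")))
  for (m in seq_along(bundle$rain))
    write_grid(bundle$rain[[m]],
               file.path(outdir, sprintf("rain_%02d.asc", m)))
  write.csv(bundle$pour_points, file.path(outdir, "pour_points.csv"),
            row.names = FALSE)
  invisible(outdir)
}

#' Command-line entry point
#'
#' `ridge2reef run --config cfg.yml --scenario deforestation --bleaching
#' high --outdir DIR` runs the full pipeline; `ridge2reef synth --seed 1
#' --size 200 --outdir DIR` writes a synthetic bundle. The per-stage
#' subcommands (`sediment`, `plume`, `drivers`, `fit`, `predict`, `assess`,
#' `prioritize`) run the pipeline through the named stage (earlier stages
#' are prerequisites and are executed as needed).
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
ridge2reef_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: ridge2reef <run|synth|sediment|plume|drivers|fit|predict|",
        "assess|prioritize> [--config cfg.yml] [--scenario S]",
        "[--bleaching B] [--seed N] [--size N] --outdir DIR\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(outdir = "r2r_out", scenario = NULL, bleaching = NULL,
              config = NULL, seed = NULL, size = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
  else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$scenario)) cfg$scenario <- opt$scenario
  if (!is.null(opt$bleaching)) cfg$bleaching <- opt$bleaching
  if (!is.null(opt$size)) cfg$synthetic$n_cells <- as.integer(opt$size)
  if (cmd == "synth") {
    b <- make_island(cfg$seed, cfg$synthetic$n_cells, cfg$synthetic$n_valleys)
    write_bundle(b, opt$outdir)
    cat("wrote synthetic bundle to ", opt$outdir, "\n")
    return(invisible(0L))
  }
  stages <- c("sediment", "plume", "drivers", "fit", "predict", "assess",
              "prioritize", "run")
  if (!cmd %in% stages) stop("unknown subcommand: ", cmd)
  run_pipeline(cfg, opt$outdir)
  cat("pipeline outputs in ", opt$outdir, "\n")
  invisible(0L)
}
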
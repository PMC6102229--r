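# Shared fixtures. The island bundle and its routed products are expensive
# enough to build once and reuse across test files (helpers are sourced once
# per test run).

.fixture_env <- new.env(parent = emptyenv())

fixture_island <- function(n_cells = 150, seed = 1) {
  key <- paste0("island_", n_cells, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_island(seed = seed, n_cells = n_cells)
  .fixture_env[[key]]
}

fixture_chain <- function(n_cells = 150, seed = 1) {
  key <- paste0("chain_", n_cells, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    b <- fixture_island(n_cells, seed)
    st <- sediment_stage(b$dem, b$rain, b$K, c_factor_grid(b$land_cover),
                         b$pour_points)
    geo <- compute_geography(b$bathy, b$coastline, "positive_down")
    pl <- plume_stage(b$bathy, geo$dist_shore, b$wind_exposure,
                      st$result$watershed_loads, b$pour_points)
    stack <- marine_driver_stack(b$bathy, b$habitat, b$coastline)
    .fixture_env[[key]] <- list(bundle = b, sediment = st, geo = geo,
                                plume = pl, stack = stack)
  }
  .fixture_env[[key]]
}

# A small inclined-plane DEM grid: elevation decreases eastward.
plane_grid <- function(n = 5, cs = 30, drop_per_cell = 1) {
  z <- matrix(rep(seq(n * drop_per_cell, drop_per_cell, by = -drop_per_cell),
                  each = n), n, n)
  r2r_grid(z, cs)
}

fast_brt <- function(seed = 1, max_trees = 300)
  brt_config(lr_grid = 0.1, tc_grid = 2, bag_grid = 0.75,
             max_trees = max_trees, folds = 5, seed = seed)
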
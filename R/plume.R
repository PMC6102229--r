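#' Plume dispersal parameters
#'
#' @param w_depth,w_dist,w_wind nonnegative weights of the three dispersal
#'   drivers (depth, distance to stream mouth, wind exposure); they must sum
#'   to 1. The composite form is this package's choice (equal thirds by
#'   default) since the source method does not state one.
#' @param max_distance_m shoreline cutoff for dispersal (3 km).
#' @param d_c cost threshold equivalent to the 3 km cutoff; `NULL` (default)
#'   auto-calibrates per pour point as the mean accumulated cost over marine
#'   cells 2,700-3,300 m from the shoreline.
#' @param cost_floor lower bound on the per-cell unit cost.
#' @return list of class `plume_params`.
#' @export
plume_params <- function(w_depth = 1 / 3, w_dist = 1 / 3, w_wind = 1 / 3,
                         max_distance_m = 3000, d_c = NULL,
                         cost_floor = 1e-3) {
  stopifnot(w_depth >= 0, w_dist >= 0, w_wind >= 0,
            abs(w_depth + w_dist + w_wind - 1) < 1e-9,
            max_distance_m > 0, is.null(d_c) || d_c > 0)
  structure(list(w_depth = w_depth, w_dist = w_dist, w_wind = w_wind,
                 max_distance_m = max_distance_m, d_c = d_c,
                 cost_floor = cost_floor), class = "plume_params")
}

minmax_norm <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < 1e-12) {
    warning("constant driver grid: its normalized contribution is set to 0")
    out <- v * 0
    return(out)
  }
  (v - rng[1]) / diff(rng)
}

#' Composite unit-cost surface for plume dispersal
#'
#' Each marine driver (depth, distance to stream mouth, wind exposure) is
#' min-max normalized to \[0, 1\] over the marine domain; the unit cost is
#' their weighted sum, floored at a small positive value so travel is never
#' free.
#'
#' @param depth,dist_to_mouth,wind_exposure aligned 60 m marine grids
#'   (`NA` = land / outside domain).
#' @param params [plume_params].
#' @return unit-cost grid.
#' @export
build_cost_surface <- function(depth, dist_to_mouth, wind_exposure,
                               params = plume_params()) {
  grid_check_aligned(depth, dist_to_mouth)
  grid_check_aligned(depth, wind_exposure)
  cost <- params$w_depth * minmax_norm(depth$values) +
    params$w_dist * minmax_norm(dist_to_mouth$values) +
    params$w_wind * minmax_norm(wind_exposure$values)
  cost <- pmax(cost, params$cost_floor)
  cost[is.na(depth$values)] <- NA
  grid_like(depth, cost)
}

#' Accumulated least-cost distance from a pour point
#'
#' Minimal accumulated cost over 8-connected paths; each step costs the
#' planimetric step length times the mean unit cost of the two cells.
#' Cells unreachable through the marine domain get `NA`.
#'
#' @param unit_cost unit-cost grid from [build_cost_surface].
#' @param pour_point `c(x, y)` map coordinates (snapped to the nearest
#'   traversable cell within one cell if it falls on land).
#' @return accumulated-cost grid (`c`), zero at the pour point.
#' @export
accumulate_cost <- function(unit_cost, pour_point) {
  nr <- nrow(unit_cost$values); nc <- ncol(unit_cost$values)
  col <- pmin(pmax(ceiling((pour_point[1] - unit_cost$origin[1]) /
                             unit_cost$cell_size), 1L), nc)
  row <- pmin(pmax(ceiling((unit_cost$origin[2] - pour_point[2]) /
                             unit_cost$cell_size), 1L), nr)
  if (is.na(unit_cost$values[row, col])) {
    # pour points sit on the shoreline: snap to nearest marine cell in a
    # small neighborhood
    found <- FALSE
    for (rad in 1:3) {
      rr <- max(1, row - rad):min(nr, row + rad)
      cc <- max(1, col - rad):min(nc, col + rad)
      sub <- unit_cost$values[rr, cc, drop = FALSE]
      if (any(!is.na(sub))) {
        w <- which(!is.na(sub), arr.ind = TRUE)[1, ]
        row <- rr[w[1]]; col <- cc[w[2]]; found <- TRUE; break
      }
    }
    if (!found) stop("pour point is not adjacent to the marine domain")
  }
  cd <- cpp_cost_distance(unit_cost$values, unit_cost$cell_size,
                          as.integer(row - 1L), as.integer(col - 1L))
  grid_like(unit_cost, cd)
}

# Auto-calibrated decay threshold: mean accumulated cost over marine cells
# in the 2,700-3,300 m shoreline band, so the decay scale matches the 3 km
# cutoff. Falls back to the band around the maximum shoreline distance when
# the domain is smaller than 3 km.
calibrate_dc <- function(cost, shoreline_dist, max_distance_m = 3000) {
  sd_v <- shoreline_dist$values
  band <- !is.na(cost$values) & !is.na(sd_v) &
    sd_v >= 0.9 * max_distance_m & sd_v <= 1.1 * max_distance_m
  if (!any(band)) {
    dmax <- max(sd_v[!is.na(cost$values)], na.rm = TRUE)
    band <- !is.na(cost$values) & !is.na(sd_v) & sd_v >= 0.9 * dmax
  }
  mean(cost$values[band], na.rm = TRUE)
}

#' Disperse a watershed's sediment load along the cost surface
#'
#' S_i = s_p * exp(-c^2 / D_c) inside the 3 km shoreline band; zero beyond.
#'
#' @param s_p sediment load (t/yr) at the pour point.
#' @param cost accumulated-cost grid from [accumulate_cost].
#' @param params [plume_params]; if `params$d_c` is `NULL` the threshold is
#'   auto-calibrated from `shoreline_dist` (see package vignette).
#' @param shoreline_dist grid of Euclidean distance (m) to the shoreline.
#' @return plume grid S (t/yr), `NA` outside the marine domain.
#' @export
disperse <- function(s_p, cost, params = plume_params(), shoreline_dist) {
  stopifnot(s_p >= 0)
  grid_check_aligned(cost, shoreline_dist)
  d_c <- if (is.null(params$d_c))
    calibrate_dc(cost, shoreline_dist, params$max_distance_m) else params$d_c
  s <- s_p * exp(-cost$values^2 / d_c)
  s[shoreline_dist$values > params$max_distance_m] <- 0
  s[is.na(cost$values) & !is.na(shoreline_dist$values)] <- 0
  grid_like(cost, s)
}

#' Sum per-watershed plumes into a TSS proxy grid
#'
#' @param plumes named list of plume grids (one per watershed).
#' @return list with `tss` (cellwise sum grid) and the input `plumes`
#'   (retained for prioritization).
#' @export
sum_plumes <- function(plumes) {
  stopifnot(length(plumes) >= 1)
  for (p in plumes) grid_check_aligned(plumes[[1]], p)
  acc <- matrix(0, nrow(plumes[[1]]$values), ncol(plumes[[1]]$values))
  na_all <- matrix(TRUE, nrow(acc), ncol(acc))
  for (p in plumes) {
    v <- p$values
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    na_all <- na_all & !ok
  }
  acc[na_all] <- NA
  list(tss = grid_like(plumes[[1]], acc), plumes = plumes)
}

#' Run the full plume stage for a set of watershed loads
#'
#' Builds the composite cost surface once, then accumulates cost and
#' disperses each watershed's pour-point load, returning per-watershed
#' plumes and the summed TSS proxy.
#'
#' @param depth,dist_shore,wind_exposure aligned 60 m marine grids; distance
#'   to each stream mouth is computed per pour point internally from the
#'   pour-point coordinates.
#' @param loads data frame with `watershed_id`, `load_t_yr`.
#' @param pour_points table with `id`, `x`, `y` matching `watershed_id`.
#' @param params [plume_params].
#' @return list of class `plume_field`: `cost` surfaces, `plumes`, `tss`,
#'   and `s_p` loads.
#' @export
plume_stage <- function(depth, dist_shore, wind_exposure, loads, pour_points,
                        params = plume_params()) {
  plumes <- list()
  costs <- list()
  for (i in seq_len(nrow(loads))) {
    wid <- loads$watershed_id[i]
    pp <- pour_points[pour_points$id == wid, , drop = FALSE]
    if (nrow(pp) != 1) stop("no pour point for watershed ", wid)
    xy <- grid_centers(depth)
    dmx <- sqrt(outer(xy$y - pp$y[1], xy$x - pp$x[1],
                      function(a, b) a^2 + b^2))
    dist_mouth <- grid_like(depth, dmx)
    dist_mouth$values[is.na(depth$values)] <- NA
    uc <- build_cost_surface(depth, dist_mouth, wind_exposure, params)
    cost <- accumulate_cost(uc, c(pp$x[1], pp$y[1]))
    plumes[[as.character(wid)]] <-
      disperse(loads$load_t_yr[i], cost, params, dist_shore)
    costs[[as.character(wid)]] <- cost
  }
  sp <- sum_plumes(plumes)
  structure(list(cost = costs, plumes = sp$plumes, tss = sp$tss,
                 s_p = stats::setNames(loads$load_t_yr,
                                       as.character(loads$watershed_id))),
            class = "plume_field")
}
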
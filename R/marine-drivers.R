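#' Geography drivers: depth and distance from shore
#'
#' @param bathy bathymetry grid over the marine domain (`NA` = land).
#' @param coastline grid whose positive cells mark the coastline (typically
#'   land cells adjacent to sea).
#' @param depth_sign either `"positive_down"` (values are depths, m) or
#'   `"negative_down"` (values are elevations, negative below sea level).
#'   Must be declared explicitly.
#' @return list with `depth` (m, >= 0 over the marine domain) and
#'   `dist_shore` (Euclidean m from the coastline; ~0 at coastal cells).
#' @export
compute_geography <- function(bathy, coastline, depth_sign = NULL) {
  if (is.null(depth_sign) ||
      !depth_sign %in% c("positive_down", "negative_down"))
    stop("depth sign convention must be declared: ",
         "'positive_down' or 'negative_down'")
  depth_v <- if (depth_sign == "positive_down") bathy$values else -bathy$values
  depth_v[depth_v < 0] <- 0
  grid_check_aligned(bathy, coastline)
  dist <- grid_distance_to(coastline)
  dist$values[is.na(bathy$values)] <- NA
  list(depth = grid_like(bathy, depth_v), dist_shore = dist)
}

#' Bathymetric position index
#'
#' BPI = local seafloor elevation minus the mean elevation over a circular
#' neighborhood of the given radius; positive on ridges and pinnacles,
#' negative in channels and depressions. (Computed on elevation = -depth so
#' the sign convention matches the benthic-terrain-modeling literature.)
#'
#' @param bathy depth grid (m, positive down).
#' @param radius_m neighborhood radius in meters (>= cell size).
#' @return BPI grid (m).
#' @export
compute_bpi <- function(bathy, radius_m) {
  stopifnot(radius_m >= bathy$cell_size)
  elev <- -bathy$values
  mu <- focal_circle_mean(elev, radius_m / bathy$cell_size)
  grid_like(bathy, elev - mu)
}

#' Terrain drivers: slope, slope of slope, and curvatures
#'
#' Slope via Horn 3x3 gradients (degrees); slope-of-slope is the same
#' operator applied to the slope grid; planar and profile curvature from the
#' local quadratic surface (second-order finite differences), with the sign
#' convention that a bowl (concave up) has positive curvature.
#'
#' @param bathy depth grid (m, positive down). Curvature is computed on the
#'   seafloor surface (elevation = -depth); slope is sign-invariant.
#' @return list with `slope` (deg), `slope_of_slope` (deg), `curv_plan` and
#'   `curv_prof` (1/m).
#' @export
compute_terrain <- function(bathy) {
  cs <- bathy$cell_size
  elev <- -bathy$values
  hs <- horn_slope(elev, cs)
  slope <- grid_like(bathy, hs$deg)
  sos <- grid_like(bathy, horn_slope(hs$deg, cs)$deg)
  p <- pad_replicate(elev)
  nr <- nrow(elev); nc <- ncol(elev)
  ctr <- shift_mat(p, 0, 0, nr, nc)
  gv <- function(dr, dc) {
    v <- shift_mat(p, dr, dc, nr, nc)
    v[is.na(v)] <- ctr[is.na(v)]
    v
  }
  zx <- hs$dzdx; zy <- hs$dzdy
  zxx <- (gv(0, 1) - 2 * ctr + gv(0, -1)) / cs^2
  zyy <- (gv(-1, 0) - 2 * ctr + gv(1, 0)) / cs^2
  zxy <- (gv(-1, 1) - gv(-1, -1) - gv(1, 1) + gv(1, -1)) / (4 * cs^2)
  g2 <- zx^2 + zy^2
  prof <- (zx^2 * zxx + 2 * zx * zy * zxy + zy^2 * zyy) /
    (g2 * (1 + g2)^1.5)
  plan <- (zy^2 * zxx - 2 * zx * zy * zxy + zx^2 * zyy) / g2^1.5
  prof[g2 < 1e-12] <- 0
  plan[g2 < 1e-12] <- 0
  prof[is.na(ctr)] <- NA; plan[is.na(ctr)] <- NA
  list(slope = slope, slope_of_slope = sos,
       curv_plan = grid_like(bathy, plan),
       curv_prof = grid_like(bathy, prof))
}

#' Exposure drivers: aspect and windowed circular statistics
#'
#' Aspect is the steepest downslope direction of the seafloor (degrees
#' clockwise from north; flat cells are `NA` and excluded from the
#' statistics). The circular mean over an odd moving window is converted to
#' northness (cosine) and eastness (sine); the circular standard deviation
#' is sqrt(-2 ln Rbar).
#'
#' @param bathy depth grid (m, positive down).
#' @param window odd window size in cells (default 3).
#' @return list with `aspect` (deg), `northness`, `eastness` (\[-1, 1\]),
#'   `aspect_circ_sd` (radians).
#' @export
compute_exposure <- function(bathy, window = 3) {
  stopifnot(window %% 2 == 1)
  elev <- -bathy$values
  asp <- horn_aspect(elev, bathy$cell_size)
  rad <- asp * pi / 180
  half <- (window - 1) / 2
  s_sin <- focal_circle_mean(sin(rad), half * sqrt(2) + 0.01)
  s_cos <- focal_circle_mean(cos(rad), half * sqrt(2) + 0.01)
  rbar <- sqrt(s_sin^2 + s_cos^2)
  mean_rad <- atan2(s_sin, s_cos)
  circ_sd <- sqrt(-2 * log(pmin(pmax(rbar, 1e-12), 1)))
  list(aspect = grid_like(bathy, asp),
       northness = grid_like(bathy, cos(mean_rad)),
       eastness = grid_like(bathy, sin(mean_rad)),
       aspect_circ_sd = grid_like(bathy, circ_sd))
}

# FRAGSTATS-style contiguity: per-cell template sum (center 1, orthogonal
# neighbors 2, diagonal neighbors 1, counting same-patch cells only),
# averaged over the patch and rescaled to [0, 1].
patch_contiguity <- function(patch_ids) {
  nr <- nrow(patch_ids); nc <- ncol(patch_ids)
  p <- matrix(NA_integer_, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- patch_ids
  ctr <- patch_ids
  val <- matrix(1, nr, nc)
  offs <- list(c(-1, -1, 1), c(-1, 0, 2), c(-1, 1, 1), c(0, -1, 2),
               c(0, 1, 2), c(1, -1, 1), c(1, 0, 2), c(1, 1, 1))
  for (o in offs) {
    nb <- p[(2 + o[1]):(nr + 1 + o[1]), (2 + o[2]):(nc + 1 + o[2])]
    same <- !is.na(nb) & !is.na(ctr) & nb == ctr
    val <- val + same * o[3]
  }
  val[is.na(ctr)] <- NA
  means <- tapply(as.vector(val), as.vector(ctr), mean)
  contig <- (means - 1) / 12
  out <- matrix(NA_real_, nr, nc)
  ok <- !is.na(ctr)
  out[ok] <- contig[as.character(ctr[ok])]
  out
}

patch_perim_area <- function(patch_ids, cell_size) {
  nr <- nrow(patch_ids); nc <- ncol(patch_ids)
  p <- matrix(NA_integer_, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- patch_ids
  ctr <- patch_ids
  edges <- matrix(0L, nr, nc)
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- p[(2 + o[1]):(nr + 1 + o[1]), (2 + o[2]):(nc + 1 + o[2])]
    diff <- is.na(nb) | is.na(ctr) | nb != ctr
    edges <- edges + (diff & !is.na(ctr))
  }
  ids <- as.vector(ctr)
  per <- tapply(as.vector(edges), ids, sum) * cell_size
  area <- tapply(rep(1, length(ids)), ids, sum) * cell_size^2
  list(perimeter = per, area = area)
}

#' Habitat-connectivity drivers from a benthic habitat class map
#'
#' Patch metrics (4-connected patches by default): contiguity (template
#' weighting, in \[0, 1\]), perimeter-area fractal dimension
#' 2 ln(0.25 P)/ln(A), and proximity (sum of area / distance^2 over
#' same-class patches whose nearest cells lie within `search_radius_m`).
#' Patch values are rasterized back to member cells. Shannon diversity
#' (-sum p ln p, nats) of class proportions is computed in a square moving
#' window.
#'
#' @param habitat integer class-code grid (`NA` outside the mapped domain).
#' @param window_m moving-window size for Shannon diversity (m).
#' @param search_radius_m proximity search radius (m).
#' @param eight_connected use 8-connected patches (default 4-connected).
#' @return list with `contiguity`, `fractal_dim`, `proximity`, `shannon`
#'   grids.
#' @export
compute_habitat_metrics <- function(habitat, window_m = 270,
                                    search_radius_m = 500,
                                    eight_connected = FALSE) {
  hv <- to_int_matrix(habitat$values)
  if (!any(!is.na(hv))) stop("empty habitat map")
  cs <- habitat$cell_size
  pid <- cpp_patches(hv, eight_connected)
  contig <- patch_contiguity(pid)
  pa <- patch_perim_area(pid, cs)
  frac <- 2 * log(0.25 * pa$perimeter) / log(pa$area)
  frac[pa$area <= cs^2] <- 1  # single-cell patches: define as 1 (line limit)
  out_frac <- matrix(NA_real_, nrow(hv), ncol(hv))
  ok <- !is.na(pid)
  out_frac[ok] <- frac[as.character(pid[ok])]
  # proximity: nearest boundary-cell distances between same-class patches
  prox <- patch_proximity(pid, hv, pa$area, cs, search_radius_m)
  out_prox <- matrix(NA_real_, nrow(hv), ncol(hv))
  out_prox[ok] <- prox[as.character(pid[ok])]
  shannon <- shannon_window(hv, max(1L, round(window_m / cs / 2)))
  list(contiguity = grid_like(habitat, contig),
       fractal_dim = grid_like(habitat, out_frac),
       proximity = grid_like(habitat, out_prox),
       shannon = grid_like(habitat, shannon))
}

# Per-patch proximity index: for each patch, sum area_j / d_j^2 over other
# patches of the same class with nearest cell-center distance d_j <= radius.
patch_proximity <- function(pid, cls, areas, cell_size, radius_m) {
  ids <- sort(unique(pid[!is.na(pid)]))
  cells <- lapply(ids, function(i) which(pid == i, arr.ind = TRUE))
  pclass <- vapply(ids, function(i) cls[pid == i][1], integer(1))
  prox <- stats::setNames(numeric(length(ids)), as.character(ids))
  if (length(ids) < 2) return(prox)
  for (a in seq_along(ids)) {
    same <- which(pclass == pclass[a])
    same <- same[same != a]
    tot <- 0
    for (b in same) {
      ca <- cells[[a]]; cb <- cells[[b]]
      d2 <- outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2
      d <- sqrt(min(d2)) * cell_size
      if (d <= radius_m && d > 0)
        tot <- tot + areas[[as.character(ids[b])]] / d^2
    }
    prox[a] <- tot
  }
  prox
}

# Shannon diversity of class proportions in a (2*half+1) square window.
shannon_window <- function(cls, half) {
  classes <- sort(unique(cls[!is.na(cls)]))
  nr <- nrow(cls); nc <- ncol(cls)
  counts <- vector("list", length(classes))
  tot <- matrix(0, nr, nc)
  box_sum <- function(m) {
    out <- matrix(0, nr, nc)
    for (dr in -half:half) for (dc in -half:half) {
      if (1 + dr > nr || nr + dr < 1 || 1 + dc > nc || nc + dc < 1) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs_ <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs_] <- out[rs, cs_] + m[rs - dr, cs_ - dc]
    }
    out
  }
  for (i in seq_along(classes)) {
    counts[[i]] <- box_sum((!is.na(cls) & cls == classes[i]) * 1)
    tot <- tot + counts[[i]]
  }
  H <- matrix(0, nr, nc)
  for (i in seq_along(classes)) {
    p <- counts[[i]] / pmax(tot, 1)
    H <- H - ifelse(p > 0, p * log(p), 0)
  }
  H[is.na(cls)] <- NA
  H
}

#' Derive the full marine driver stack
#'
#' @param bathy depth grid (m, positive down, `NA` on land).
#' @param habitat benthic habitat class grid aligned with `bathy`.
#' @param coastline coastline mask grid.
#' @param exposure_window odd window (cells) for the circular statistics.
#' @param shannon_window_m Shannon moving-window size (m).
#' @param proximity_radius_m proximity search radius (m).
#' @return named list of aligned driver grids (see vignette for the roster).
#' @export
marine_driver_stack <- function(bathy, habitat, coastline,
                                exposure_window = 3, shannon_window_m = 270,
                                proximity_radius_m = 500) {
  geo <- compute_geography(bathy, coastline, depth_sign = "positive_down")
  terr <- compute_terrain(bathy)
  expo <- compute_exposure(bathy, exposure_window)
  hab <- compute_habitat_metrics(habitat, shannon_window_m,
                                 proximity_radius_m)
  c(list(depth = geo$depth, dist_shore = geo$dist_shore,
         bpi_60 = compute_bpi(bathy, 60), bpi_240 = compute_bpi(bathy, 240)),
    terr, expo[c("aspect", "northness", "eastness", "aspect_circ_sd")], hab)
}
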
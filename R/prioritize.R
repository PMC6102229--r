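#' Link impacted reef areas to the watersheds supplying their sediment
#'
#' Sums each watershed's plume over the significant reef cells, ranks the
#' watersheds by contribution, and returns the smallest prefix of that
#' ranking whose cumulative share of the total exceeds the threshold
#' (default > 90%).
#'
#' @param sig_reef_mask significance grid (60 m) from [sig_diff].
#' @param plumes named list of per-watershed plume grids.
#' @param threshold cumulative contribution threshold (default 0.90).
#' @return list with `linked` (watershed ids), and `contributions` data
#'   frame (`watershed_id`, `contribution`, `fraction`, `linked_flag`).
#' @export
link_watersheds <- function(sig_reef_mask, plumes, threshold = 0.90) {
  m <- sig_reef_mask$values > 0 & !is.na(sig_reef_mask$values)
  contrib <- vapply(plumes, function(p) {
    grid_check_aligned(sig_reef_mask, p)
    sum(p$values[m], na.rm = TRUE)
  }, numeric(1))
  total <- sum(contrib)
  if (!any(m) || total <= 0) {
    if (!any(m))
      return(list(linked = character(0),
                  contributions = data.frame(watershed_id = names(plumes),
                                             contribution = contrib,
                                             fraction = contrib * 0,
                                             linked_flag = FALSE)))
    stop("total plume load over the significant reef area is zero")
  }
  ord <- order(contrib, decreasing = TRUE)
  frac <- contrib / total
  cum <- cumsum(frac[ord])
  k <- which(cum > threshold)[1]
  linked_idx <- ord[seq_len(k)]
  df <- data.frame(watershed_id = names(plumes), contribution = contrib,
                   fraction = frac,
                   linked_flag = seq_along(plumes) %in% linked_idx)
  list(linked = names(plumes)[linked_idx], contributions = df)
}

#' Priority land areas within linked watersheds
#'
#' Climate mode: within each linked watershed, cells are ranked by
#' current-land-use sediment export (ties broken by higher flow
#' accumulation, then row-major order) and the smallest top set whose
#' cumulative export exceeds `frac` (default > 66%) of the watershed total
#' is selected. Land-use mode: the selected cells are those of the linked
#' watersheds whose export difference against present is significant at
#' `alpha` (via [sig_diff] computed over the linked-watershed cells).
#'
#' @param export_current current-scenario export grid (30 m).
#' @param watersheds `watershed_set` (supplies labels).
#' @param linked_ids watershed ids from [link_watersheds].
#' @param mode `"climate"` or `"landuse"`.
#' @param frac cumulative-export fraction for climate mode.
#' @param export_scenario scenario export grid (required in landuse mode).
#' @param alpha significance level for landuse mode.
#' @param flow_accum accumulation grid used for tie-breaking.
#' @return priority mask grid (30 m, 1 = priority).
#' @export
priority_land_areas <- function(export_current, watersheds, linked_ids,
                                mode = c("climate", "landuse"), frac = 0.66,
                                export_scenario = NULL, alpha = 0.10,
                                flow_accum = NULL) {
  mode <- match.arg(mode)
  if (!length(linked_ids)) stop("linked watershed set is empty")
  lab <- watersheds$labels$values
  linked_codes <- as.numeric(linked_ids)
  mask <- matrix(0, nrow(lab), ncol(lab))
  if (mode == "climate") {
    ev <- export_current$values
    fa <- if (is.null(flow_accum)) matrix(0, nrow(lab), ncol(lab))
    else flow_accum$values
    for (w in linked_codes) {
      cells <- which(lab == w & !is.na(lab) & !is.na(ev))
      if (!length(cells)) next
      tot <- sum(ev[cells])
      if (tot <= 0) next
      ord <- order(-ev[cells], -fa[cells], cells)
      cum <- cumsum(ev[cells][ord])
      k <- which(cum > frac * tot)[1]
      mask[cells[ord[seq_len(k)]]] <- 1
    }
  } else {
    if (is.null(export_scenario)) stop("landuse mode needs a scenario export grid")
    in_linked <- lab %in% linked_codes & !is.na(lab)
    cur <- grid_like(export_current,
                     ifelse(in_linked, export_current$values, NA))
    scn <- grid_like(export_current,
                     ifelse(in_linked, export_scenario$values, NA))
    sd_res <- sig_diff(scn, cur, alpha)
    mask[sd_res$significant$values > 0 & !is.na(sd_res$significant$values)] <- 1
  }
  mask[is.na(lab)] <- NA
  grid_like(watersheds$labels, mask)
}

#' Buffer priority cells by a fixed distance and polygonize
#'
#' Dilates the 30 m priority mask by `distance_m` (exact Euclidean distance
#' transform on a 10 m subgrid, so buffered squares get properly rounded
#' corners) and traces the result into polygons. A lone 30 m cell yields a
#' rounded square of area approximately a^2 + 4 a r + pi r^2.
#'
#' @param mask priority mask grid (positive = priority).
#' @param distance_m buffer distance (default 100 m).
#' @param subcell_m subgrid resolution for the dilation (default 10 m).
#' @param clip_to optional grid; buffered cells where `clip_to` is `NA`
#'   (e.g. ocean) are removed.
#' @return list of class `priority_polygons`: `polygons` (list of rings in
#'   map coordinates; first ring outer, rest holes), `area_m2` per polygon,
#'   and `mask_fine` (the buffered subgrid).
#' @export
buffer_priority <- function(mask, distance_m = 100, subcell_m = 10,
                            clip_to = NULL) {
  mv <- mask$values > 0 & !is.na(mask$values)
  f <- as.integer(round(mask$cell_size / subcell_m))
  stopifnot(f >= 1)
  nrf <- nrow(mv) * f; ncf <- ncol(mv) * f
  if (!any(mv)) {
    return(structure(list(polygons = list(), area_m2 = numeric(0),
                          mask_fine = NULL), class = "priority_polygons"))
  }
  fine <- matrix(0L, nrf, ncf)
  idx <- which(mv, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    rs <- ((idx[i, 1] - 1) * f + 1):(idx[i, 1] * f)
    cs <- ((idx[i, 2] - 1) * f + 1):(idx[i, 2] * f)
    fine[rs, cs] <- 1L
  }
  d <- sqrt(cpp_edt_sq(fine)) * subcell_m
  buf <- d <= distance_m
  if (!is.null(clip_to)) {
    keep <- !is.na(clip_to$values)
    keep_fine <- keep[rep(seq_len(nrow(keep)), each = f),
                      rep(seq_len(ncol(keep)), each = f)]
    buf <- buf & keep_fine
  }
  fine_grid <- r2r_grid(buf * 1, subcell_m, origin = mask$origin,
                        crs = mask$crs)
  polys <- polygonize_mask(buf, subcell_m, mask$origin)
  structure(list(polygons = polys$polygons, area_m2 = polys$area_m2,
                 mask_fine = fine_grid), class = "priority_polygons")
}

# Trace the boundary rings of a binary matrix into polygons.
# Returns one polygon per 8-connected component; each polygon is a list of
# rings (x/y matrices), the largest-|area| ring first (outer boundary).
polygonize_mask <- function(b, cell_size, origin) {
  nr <- nrow(b); nc <- ncol(b)
  comp <- cpp_patches(to_int_matrix(b * 1), eight = TRUE)
  comp[b == 0] <- NA
  cells <- which(b, arr.ind = TRUE)
  if (!nrow(cells)) return(list(polygons = list(), area_m2 = numeric(0)))
  # directed boundary edges, interior on the left (CCW outer rings in map
  # coordinates with y up). Vertex (i, j) = corner x0 + i*h, y0 - j*h,
  # i in 0..nc, j in 0..nr.
  vid <- function(i, j) j * (nc + 1) + i + 1
  starts <- integer(0); ends <- integer(0); ecomp <- integer(0)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && b[r, c]
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]; c <- cells[k, 2]; cp <- comp[r, c]
    # corners: NW=(c-1, r-1) NE=(c, r-1) SE=(c, r) SW=(c-1, r)
    if (!at(r + 1, c)) { # south edge: SW -> SE
      starts <- c(starts, vid(c - 1, r)); ends <- c(ends, vid(c, r))
      ecomp <- c(ecomp, cp)
    }
    if (!at(r, c + 1)) { # east edge: SE -> NE
      starts <- c(starts, vid(c, r)); ends <- c(ends, vid(c, r - 1))
      ecomp <- c(ecomp, cp)
    }
    if (!at(r - 1, c)) { # north edge: NE -> NW
      starts <- c(starts, vid(c, r - 1)); ends <- c(ends, vid(c - 1, r - 1))
      ecomp <- c(ecomp, cp)
    }
    if (!at(r, c - 1)) { # west edge: NW -> SW
      starts <- c(starts, vid(c - 1, r - 1)); ends <- c(ends, vid(c - 1, r))
      ecomp <- c(ecomp, cp)
    }
  }
  used <- rep(FALSE, length(starts))
  # index edges by start vertex
  by_start <- split(seq_along(starts), starts)
  rings <- list(); ring_comp <- integer(0)
  for (e0 in seq_along(starts)) {
    if (used[e0]) next
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      nxt <- by_start[[as.character(ends[e])]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      e <- nxt[1]
    }
    # vertices of the ring
    vs <- c(starts[path], ends[path[length(path)]])
    i <- (vs - 1) %% (nc + 1)
    j <- (vs - 1) %/% (nc + 1)
    x <- origin[1] + i * cell_size
    y <- origin[2] - j * cell_size
    rings[[length(rings) + 1]] <- cbind(x = x, y = y)
    ring_comp <- c(ring_comp, ecomp[e0])
  }
  shoelace <- function(m) {
    x <- m[, 1]; y <- m[, 2]
    0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  }
  polys <- list(); areas <- numeric(0)
  for (cp in sort(unique(ring_comp))) {
    rs <- rings[ring_comp == cp]
    a <- vapply(rs, shoelace, numeric(1))
    ordr <- order(-abs(a))
    polys[[length(polys) + 1]] <- rs[ordr]
    areas <- c(areas, abs(a[ordr[1]]) - sum(abs(a[ordr[-1]])))
  }
  list(polygons = polys, area_m2 = areas)
}

#' Write priority polygons as GeoJSON
#' @param pp a `priority_polygons` object.
#' @param path output `.geojson` path.
#' @param properties optional data frame of per-polygon properties.
#' @export
write_priority_geojson <- function(pp, path, properties = NULL) {
  feats <- lapply(seq_along(pp$polygons), function(i) {
    rings <- lapply(pp$polygons[[i]], function(m) {
      m2 <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m2)), function(k) c(m2[k, 1], m2[k, 2]))
    })
    props <- list(area_m2 = pp$area_m2[i])
    if (!is.null(properties)) props <- c(props, as.list(properties[i, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
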
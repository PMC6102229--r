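#' Sediment delivery parameters
#'
#' Calibration constants for the connectivity-index / sediment-delivery-ratio
#' model. Defaults follow the published calibration for the Kubulau case
#' study: IC0 = 0.5, Borselli k = 2.0, maximum SDR = 0.8, and a fallback
#' erodibility of 0.002 ton.ha.hr/(MJ.ha.mm) for soils missing K values.
#'
#' @param ic0 connectivity calibration constant (logistic midpoint).
#' @param k_borselli logistic shape factor (> 0).
#' @param sdr_max maximum allowable delivery ratio, in (0, 1].
#' @param flow_accum_threshold flow-accumulation threshold (cells) defining
#'   streams.
#' @param k_fill fallback soil erodibility for nodata K cells.
#' @return list of class `sdr_params`.
#' @export
sdr_params <- function(ic0 = 0.5, k_borselli = 2.0, sdr_max = 0.8,
                       flow_accum_threshold = 50, k_fill = 0.002) {
  stopifnot(sdr_max > 0, sdr_max <= 1, k_borselli > 0,
            flow_accum_threshold >= 1, k_fill >= 0)
  structure(list(ic0 = ic0, k_borselli = k_borselli, sdr_max = sdr_max,
                 flow_accum_threshold = flow_accum_threshold, k_fill = k_fill),
            class = "sdr_params")
}

bols_erosivity <- function(P) 2.5 * P^2 / (100 * (0.073 * P + 0.73))

#' Rainfall erosivity from precipitation (Bols method)
#'
#' Converts precipitation (mm) to rainfall erosivity R
#' (MJ.mm.ha^-1.hr^-1) with the Bols empirical relation
#' R = 2.5 P^2 / (100 (0.073 P + 0.73)), applied per month and summed
#' (`mode = "monthly"`) or applied once to the annual total
#' (`mode = "annual"`).
#'
#' @param p_rain a single precipitation grid, or a list of monthly grids.
#' @param mode `"monthly"` or `"annual"`.
#' @return erosivity grid.
#' @export
compute_erosivity <- function(p_rain, mode = c("monthly", "annual")) {
  mode <- match.arg(mode)
  grids <- if (is_grid(p_rain)) list(p_rain) else p_rain
  stopifnot(length(grids) >= 1)
  for (g in grids) {
    if (any(g$values < 0, na.rm = TRUE)) stop("negative precipitation")
    grid_check_aligned(grids[[1]], g)
  }
  if (mode == "monthly") {
    acc <- matrix(0, nrow(grids[[1]]$values), ncol(grids[[1]]$values))
    for (g in grids) acc <- acc + bols_erosivity(g$values)
  } else {
    tot <- Reduce(`+`, lapply(grids, function(g) g$values))
    acc <- bols_erosivity(tot)
  }
  grid_like(grids[[1]], acc)
}

#' Depression-fill a DEM and derive D8 flow routing
#'
#' Fills closed depressions by priority-flood (with a tiny elevation
#' increment so every land cell gains a strict downslope path to the sea),
#' then assigns D8 steepest-descent flow directions and counts upstream
#' contributing cells (including the cell itself). `NA` cells are ocean.
#'
#' @param dem elevation grid (m); `NA` = ocean.
#' @return list with `filled` (grid), `flow_dir` (grid of D8 codes 0-7 =
#'   E,SE,S,SW,W,NW,N,NE; -1 = drains directly to sea), and `flow_accum`
#'   (grid of upstream cell counts).
#' @export
fill_and_route <- function(dem) {
  stopifnot(is_grid(dem))
  if (cpp_all_flat(dem$values))
    stop("degenerate terrain: DEM is entirely flat (no outlet)")
  filled <- cpp_fill_depressions(dem$values)
  fd <- cpp_d8_flowdir(filled)
  acc <- cpp_flow_accum(fd)
  list(filled = grid_like(dem, filled),
       flow_dir = grid_like(dem, fd),
       flow_accum = grid_like(dem, acc))
}

#' Delineate streams from flow accumulation
#' @param flow_accum accumulation grid from [fill_and_route].
#' @param threshold accumulation (cells) at or above which a cell is stream.
#' @return logical-valued grid (1 = stream).
#' @export
delineate_streams <- function(flow_accum, threshold) {
  stopifnot(threshold >= 1)
  grid_like(flow_accum, (flow_accum$values >= threshold) * 1)
}

#' Delineate watersheds draining to coastal pour points
#'
#' Labels every land cell by the pour point its D8 flow path reaches;
#' cells draining elsewhere (minor coastal fringes) are labeled 0
#' ("unassigned").
#'
#' @param flow_dir D8 direction grid from [fill_and_route].
#' @param pour_points data frame with `id`, `x`, `y` (map coordinates of
#'   shoreline outlet cells).
#' @return list of class `watershed_set`: `labels` grid (integer codes
#'   matching `pour_points$id`) and the `pour_points` table augmented with
#'   `row`/`col`.
#' @export
delineate_watersheds <- function(flow_dir, pour_points) {
  stopifnot(all(c("x", "y") %in% names(pour_points)))
  pp <- as.data.frame(pour_points)
  if (is.null(pp$id)) pp$id <- seq_len(nrow(pp))
  nr <- nrow(flow_dir$values); nc <- ncol(flow_dir$values)
  col <- pmin(pmax(ceiling((pp$x - flow_dir$origin[1]) / flow_dir$cell_size), 1L), nc)
  row <- pmin(pmax(ceiling((flow_dir$origin[2] - pp$y) / flow_dir$cell_size), 1L), nr)
  if (anyDuplicated(cbind(row, col))) stop("duplicate pour points in one cell")
  lab <- cpp_watershed_label(flow_dir$values |> to_int_matrix(),
                             as.integer(row - 1L), as.integer(col - 1L))
  labv <- matrix(as.numeric(lab), nr, nc)
  # map 1..K to pour point ids
  remap <- labv
  pos <- labv > 0 & !is.na(labv)
  remap[pos] <- pp$id[labv[pos]]
  pp$row <- row; pp$col <- col
  structure(list(labels = grid_like(flow_dir, remap), pour_points = pp),
            class = "watershed_set")
}

to_int_matrix <- function(m) {
  out <- m
  storage.mode(out) <- "integer"
  out
}

#' Slope-length/gradient (LS) factor, Desmet-Govers form
#'
#' Two-dimensional LS from per-cell slope (Horn) and upslope contributing
#' area at the cell inlet: LS = S * ((A + D^2)^(m+1) - A^(m+1)) /
#' (D^(m+2) x^m 22.13^m), with the McCool slope factor S and the
#' area exponent m = beta/(1+beta). The result is capped at
#' 333 * tan(slope)^0.83 (and optionally a fixed ceiling), which also sends
#' flat cells to ~0.
#'
#' @param dem elevation grid (filled or raw).
#' @param flow_accum contributing-cell counts from [fill_and_route].
#' @param ls_ceiling optional absolute LS cap (default `Inf`).
#' @return LS grid (dimensionless).
#' @export
compute_ls <- function(dem, flow_accum, ls_ceiling = Inf) {
  grid_check_aligned(dem, flow_accum)
  cs <- dem$cell_size
  hs <- horn_slope(dem$values, cs)
  theta <- atan(hs$tan)
  sin_t <- sin(theta)
  S <- ifelse(hs$tan < 0.09, 10.8 * sin_t + 0.03, 16.8 * sin_t - 0.5)
  beta <- (sin_t / 0.0896) / (3 * sin_t^0.8 + 0.56)
  m <- beta / (1 + beta)
  A_in <- pmax(flow_accum$values - 1, 0) * cs^2
  asp <- horn_aspect(dem$values, cs)
  x <- abs(sin(asp * pi / 180)) + abs(cos(asp * pi / 180))
  x[is.na(x)] <- 1
  ls <- S * ((A_in + cs^2)^(m + 1) - A_in^(m + 1)) /
    (cs^(m + 2) * x^m * 22.13^m)
  cap <- pmin(333 * hs$tan^0.83, ls_ceiling)
  ls <- pmin(ls, cap)
  ls[is.na(dem$values)] <- NA
  grid_like(dem, ls)
}

#' Per-cell annual soil loss (RUSLE)
#'
#' Soil loss = R * K * LS * C * P * cell_area, with the management-practice
#' factor P fixed at 1 (excluded for lack of data).
#'
#' @param factors list with grids `R`, `K`, `LS`, `C` (aligned); optional
#'   scalar `P_practice` (default 1).
#' @param cell_area_ha cell area in hectares (0.09 for 30 m cells).
#' @param k_fill fallback erodibility substituted where K is `NA` but other
#'   factors are defined.
#' @return soil loss grid (t per cell per year).
#' @export
compute_rusle <- function(factors, cell_area_ha, k_fill = 0.002) {
  with(factors, {
    grid_check_aligned(R, K); grid_check_aligned(R, LS); grid_check_aligned(R, C)
    if (any(C$values > 1 + 1e-9, na.rm = TRUE)) stop("C-factor must be <= 1")
    Kv <- K$values
    fill_me <- is.na(Kv) & !is.na(R$values)
    Kv[fill_me] <- k_fill
    p_practice <- if (!is.null(factors$P_practice)) factors$P_practice else 1
    loss <- R$values * Kv * LS$values * C$values * p_practice * cell_area_ha
    grid_like(R, loss)
  })
}

#' Hydrologic connectivity index (Borselli IC)
#'
#' IC_i = log10(D_up / D_dn) with D_up = Cbar * Sbar * sqrt(A) over the
#' upslope contributing area (including the cell), and D_dn the sum of
#' d_j / (C_j S_j) along the D8 flow path down to the nearest stream cell.
#' Slope is floored at 0.005 m/m and C at `c_floor` to avoid singular
#' weights. Stream cells and cells with no path to a stream get `NA`.
#'
#' @param dem elevation grid (filled).
#' @param C cover-factor grid.
#' @param flow_dir D8 direction grid.
#' @param streams stream mask grid.
#' @param slope_floor minimum slope (m/m) used in both terms.
#' @param c_floor minimum C used in the weights.
#' @return IC grid.
#' @export
compute_connectivity <- function(dem, C, flow_dir, streams,
                                 slope_floor = 0.005, c_floor = 0.001) {
  grid_check_aligned(dem, C); grid_check_aligned(dem, flow_dir)
  grid_check_aligned(dem, streams)
  cs <- dem$cell_size
  S <- pmax(horn_slope(dem$values, cs)$tan, slope_floor)
  Cw <- pmax(C$values, c_floor)
  fd <- to_int_matrix(flow_dir$values)
  ones <- matrix(1, nrow(dem$values), ncol(dem$values))
  ones[is.na(dem$values)] <- NA
  n_up <- cpp_upslope_sum(fd, ones)
  c_up <- cpp_upslope_sum(fd, ifelse(is.na(Cw), 0, Cw))
  s_up <- cpp_upslope_sum(fd, ifelse(is.na(S), 0, S))
  A <- n_up * cs^2
  d_up <- (c_up / n_up) * (s_up / n_up) * sqrt(A)
  # downslope: step length through each cell over C*S
  step_len <- matrix(cs, nrow(fd), ncol(fd))
  diag_dirs <- fd %in% c(1L, 3L, 5L, 7L)
  step_len[diag_dirs] <- cs * sqrt(2)
  w_dn <- step_len / (Cw * S)
  sm <- streams$values > 0 & !is.na(streams$values)
  d_dn <- cpp_downslope_sum(fd, w_dn, sm)
  ic <- log10(pmax(d_up, 1e-300) / d_dn)
  ic[sm] <- NA          # stream cells excluded (delivery handled in export)
  ic[is.na(d_dn)] <- NA # no path to a stream
  grid_like(dem, ic)
}

#' Sediment delivery ratio from connectivity
#'
#' SDR_i = sdr_max / (1 + exp((IC0 - IC_i) / k)). At IC = IC0 the ratio is
#' half the maximum; the asymptotes are 0 and `sdr_max`.
#'
#' @param ic connectivity-index grid.
#' @param params [sdr_params].
#' @return SDR grid.
#' @export
compute_sdr <- function(ic, params = sdr_params()) {
  sdr <- params$sdr_max / (1 + exp((params$ic0 - ic$values) / params$k_borselli))
  grid_like(ic, sdr)
}

#' Sediment export and per-watershed loads
#'
#' Export_i = soil_loss_i * SDR_i (cells without a defined SDR export
#' nothing); watershed loads are the per-label sums of export.
#'
#' @param soil_loss RUSLE soil-loss grid (t/yr per cell).
#' @param sdr delivery-ratio grid.
#' @param watersheds a `watershed_set` from [delineate_watersheds].
#' @return list of class `sediment_result`: `export` grid, `watershed_loads`
#'   data frame (`watershed_id`, `area_ha`, `load_t_yr`), and `total_t_yr`.
#' @export
compute_export <- function(soil_loss, sdr, watersheds) {
  grid_check_aligned(soil_loss, sdr)
  grid_check_aligned(soil_loss, watersheds$labels)
  exp_v <- soil_loss$values * sdr$values
  exp_v[is.na(sdr$values) & !is.na(soil_loss$values)] <- 0
  lab <- watersheds$labels$values
  cell_ha <- (soil_loss$cell_size^2) / 1e4
  ids <- sort(unique(lab[lab > 0 & !is.na(lab)]))
  loads <- vapply(ids, function(i)
    sum(exp_v[lab == i & !is.na(lab)], na.rm = TRUE), numeric(1))
  areas <- vapply(ids, function(i) sum(lab == i, na.rm = TRUE) * cell_ha,
                  numeric(1))
  structure(list(
    export = grid_like(soil_loss, exp_v),
    watershed_loads = data.frame(watershed_id = ids, area_ha = areas,
                                 load_t_yr = loads),
    total_t_yr = sum(exp_v, na.rm = TRUE)
  ), class = "sediment_result")
}

#' Run the full sediment-export stage
#'
#' Convenience wrapper chaining erosivity, routing, streams, watersheds,
#' LS, RUSLE, connectivity, SDR, and export.
#'
#' @param dem elevation grid (30 m; `NA` = ocean).
#' @param rain_monthly list of monthly precipitation grids (mm).
#' @param K erodibility grid.
#' @param C cover-factor grid.
#' @param pour_points pour-point table (`id`, `x`, `y`).
#' @param params [sdr_params].
#' @param erosivity_mode `"monthly"` or `"annual"`.
#' @return list with all intermediate grids, the `watershed_set` and the
#'   `sediment_result`.
#' @export
sediment_stage <- function(dem, rain_monthly, K, C, pour_points,
                           params = sdr_params(),
                           erosivity_mode = "monthly") {
  R <- compute_erosivity(rain_monthly, erosivity_mode)
  rt <- fill_and_route(dem)
  streams <- delineate_streams(rt$flow_accum, params$flow_accum_threshold)
  ws <- delineate_watersheds(rt$flow_dir, pour_points)
  LS <- compute_ls(rt$filled, rt$flow_accum)
  cell_ha <- dem$cell_size^2 / 1e4
  loss <- compute_rusle(list(R = R, K = K, LS = LS, C = C), cell_ha,
                        k_fill = params$k_fill)
  ic <- compute_connectivity(rt$filled, C, rt$flow_dir, streams)
  sdr <- compute_sdr(ic, params)
  res <- compute_export(loss, sdr, ws)
  list(R = R, routing = rt, streams = streams, watersheds = ws, LS = LS,
       soil_loss = loss, ic = ic, sdr = sdr, result = res)
}
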
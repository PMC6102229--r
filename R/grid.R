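#' Georeferenced raster grid
#'
#' Minimal single-band raster container used throughout the pipeline. Values
#' are stored as a numeric (or integer class-code) matrix in row-major map
#' order: row 1 is the northernmost row, column 1 the westernmost column.
#' Cell centers represent cell location; `origin` is the map coordinate of the
#' upper-left corner of the upper-left cell. Missing data are stored as `NA`
#' internally and serialized using the `nodata` sentinel.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell_size cell edge length in meters (> 0).
#' @param origin length-2 numeric `c(x, y)`: map coordinates of the upper-left
#'   corner. Defaults to `c(0, nrow(values) * cell_size)` so the lower-left
#'   corner sits at (0, 0).
#' @param crs opaque coordinate reference identifier (carried, never
#'   transformed).
#' @param nodata sentinel written to disk for `NA` cells.
#' @return an object of class `r2r_grid`.
#' @export
r2r_grid <- function(values, cell_size, origin = NULL, crs = "local-meters",
                     nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  if (is.null(origin)) origin <- c(0, nrow(values) * cell_size)
  stopifnot(length(origin) == 2L)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = as.character(crs),
         nodata = as.numeric(nodata)),
    class = "r2r_grid"
  )
}

#' @export
print.r2r_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<r2r_grid> %d x %d cells @ %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2], x$crs))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g], %d NA\n", min(fin), max(fin), sum(is.na(v))))
  } else cat("  values: all NA\n")
  invisible(x)
}

#' @export
dim.r2r_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "r2r_grid")

#' Check that two grids share shape, origin and cell size
#' @param a,b grids.
#' @param tol positional tolerance in meters.
#' @return `TRUE` invisibly; signals an error otherwise.
#' @export
grid_check_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(is_grid(a), is_grid(b))
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids are not aligned: shapes differ")
  if (abs(a$cell_size - b$cell_size) > tol)
    stop("grids are not aligned: cell sizes differ")
  if (any(abs(a$origin - b$origin) > tol))
    stop("grids are not aligned: origins differ")
  invisible(TRUE)
}

#' Map coordinates of cell centers
#' @param g grid.
#' @return list with `x` (by column) and `y` (by row) center coordinates.
#' @export
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(x = g$origin[1] + (seq_len(nc) - 0.5) * g$cell_size,
       y = g$origin[2] - (seq_len(nr) - 0.5) * g$cell_size)
}

#' Construct a grid like another, with new values
#' @param g template grid.
#' @param values matrix of the same shape (defaults to all-NA).
#' @export
grid_like <- function(g, values = NULL) {
  if (is.null(values))
    values <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  r2r_grid(values, g$cell_size, g$origin, g$crs, g$nodata)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Reads `.asc` rasters (a plain-text interchange format understood by every
#' GIS). A sidecar `<path>.prj` file, if present, supplies the CRS string.
#' When `target_cell_size` is given the raster is resampled: bilinear for
#' continuous values (the default) or nearest-neighbor for class codes.
#'
#' @param path path to the `.asc` file.
#' @param target_cell_size optional cell size (m) to resample to.
#' @param method `"bilinear"` or `"nearest"`.
#' @param expect_crs optional CRS string; a mismatch with the file's sidecar
#'   CRS signals a configuration error.
#' @return an [r2r_grid].
#' @export
read_grid <- function(path, target_cell_size = NULL,
                      method = c("bilinear", "nearest"), expect_crs = NULL) {
  method <- match.arg(method)
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated ASCII grid: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else { seek(con, pos); break }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("bad ASCII grid header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc) stop("wrong cell count in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  crs <- "local-meters"
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) crs <- trimws(readLines(prj, n = 1L, warn = FALSE))
  if (!is.null(expect_crs) && !identical(crs, expect_crs))
    stop("CRS mismatch: file '", path, "' has '", crs, "', expected '",
         expect_crs, "'")
  g <- r2r_grid(m, cs, origin = c(xll, yll + nr * cs), crs = crs,
                nodata = nodata)
  if (!is.null(target_cell_size) && abs(target_cell_size - cs) > 1e-9)
    g <- grid_resample(g, target_cell_size, method)
  g
}

#' Write a grid to an ESRI ASCII file (with CRS sidecar)
#'
#' Values round-trip bit-exactly for float32-representable data because they
#' are printed with 17 significant digits. `NA` cells are written as the
#' grid's `nodata` sentinel.
#'
#' @param grid an [r2r_grid].
#' @param path output path (`.asc`); parent directory must exist.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_grid(grid))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", grid$origin[1]),
    sprintf("yllcorner %.10f", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.10f", grid$cell_size),
    sprintf("NODATA_value %g", grid$nodata)
  )
  out <- v
  out[is.na(out)] <- grid$nodata
  rows <- apply(out, 1L, function(r) paste(formatC(r, digits = 17, format = "g"),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Resample a grid to a new cell size
#'
#' Bilinear interpolation for continuous fields, nearest neighbor for class
#' codes. The output covers the same extent (snapped so the extent is an
#' integer number of output cells, anchored at the upper-left origin).
#'
#' @param g input grid.
#' @param cell_size target cell size (m).
#' @param method `"bilinear"` or `"nearest"`.
#' @return resampled [r2r_grid].
#' @export
grid_resample <- function(g, cell_size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nr_in <- nrow(g$values); nc_in <- ncol(g$values)
  width <- nc_in * g$cell_size; height <- nr_in * g$cell_size
  nc_out <- max(1L, as.integer(round(width / cell_size)))
  nr_out <- max(1L, as.integer(round(height / cell_size)))
  xo <- g$origin[1] + (seq_len(nc_out) - 0.5) * cell_size
  yo <- g$origin[2] - (seq_len(nr_out) - 0.5) * cell_size
  vals <- if (method == "nearest") {
    ci <- pmin(pmax(ceiling((xo - g$origin[1]) / g$cell_size), 1L), nc_in)
    ri <- pmin(pmax(ceiling((g$origin[2] - yo) / g$cell_size), 1L), nr_in)
    g$values[ri, ci, drop = FALSE]
  } else {
    bilinear_sample_matrix(g, rep(xo, each = nr_out), rep(yo, times = nc_out)) |>
      matrix(nrow = nr_out, ncol = nc_out)
  }
  r2r_grid(vals, cell_size, g$origin, g$crs, g$nodata)
}

# Bilinear interpolation of grid values at arbitrary map coordinates.
# Outside-edge points are clamped to the border cell centers; a point with any
# NA corner contribution returns NA (weight renormalization is deliberately
# not done so that survey points in nodata neighborhoods are flagged).
bilinear_sample_matrix <- function(g, x, y) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  # fractional column/row position in cell-center units
  fc <- (x - g$origin[1]) / g$cell_size + 0.5
  fr <- (g$origin[2] - y) / g$cell_size + 0.5
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L); c0 <- pmax(c0, 1L)
  r0 <- pmin(floor(fr), nr - 1L); r0 <- pmax(r0, 1L)
  tx <- fc - c0; ty <- fr - r0
  if (nc == 1L) { c0 <- rep(1L, length(x)); tx <- rep(0, length(x)) }
  if (nr == 1L) { r0 <- rep(1L, length(y)); ty <- rep(0, length(y)) }
  idx <- function(r, c) v[cbind(r, c)]
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  # corners with zero weight must not inject NA (points sitting exactly on
  # a cell center only depend on that cell)
  term <- function(w, val) ifelse(w == 0, 0, w * val)
  term((1 - tx) * (1 - ty), idx(r0, c0)) +
    term(tx * (1 - ty), idx(r0, c1)) +
    term((1 - tx) * ty, idx(r1, c0)) +
    term(tx * ty, idx(r1, c1))
}

#' Sample a grid at point coordinates
#' @param g grid.
#' @param x,y map coordinates.
#' @param method `"bilinear"` (continuous) or `"nearest"` (class codes).
#' @return numeric vector of sampled values (`NA` where undefined).
#' @export
grid_sample <- function(g, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "bilinear") return(bilinear_sample_matrix(g, x, y))
  nr <- nrow(g$values); nc <- ncol(g$values)
  ci <- pmin(pmax(ceiling((x - g$origin[1]) / g$cell_size), 1L), nc)
  ri <- pmin(pmax(ceiling((g$origin[2] - y) / g$cell_size), 1L), nr)
  g$values[cbind(ri, ci)]
}

#' Euclidean distance to the nearest TRUE cell
#'
#' Exact squared Euclidean distance transform (two-pass
#' Felzenszwalb-Huttenlocher), returned in meters from cell center to the
#' nearest target cell center.
#'
#' @param mask logical matrix or grid of target cells.
#' @param template grid supplying georeferencing when `mask` is a matrix.
#' @return grid of distances (m); `Inf` when the mask is empty.
#' @export
grid_distance_to <- function(mask, template = NULL) {
  if (is_grid(mask)) { template <- mask; m <- mask$values > 0 & !is.na(mask$values) }
  else m <- mask
  stopifnot(!is.null(template))
  d2 <- cpp_edt_sq(m * 1L)
  grid_like(template, sqrt(d2) * template$cell_size)
}

#' Point table
#'
#' Survey/point data container: a data frame with `id`, `x`, `y` and named
#' attribute columns, plus a declared domain extent.
#'
#' @param df data frame with at least `x` and `y` columns.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   bounding box. Points must fall inside the extent.
#' @return a `r2r_points` data frame.
#' @export
r2r_points <- function(df, extent = NULL) {
  stopifnot(all(c("x", "y") %in% names(df)))
  if (anyDuplicated(names(df))) stop("attribute names must be unique")
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  if (is.null(extent)) extent <- c(range(df$x), range(df$y))
  if (any(df$x < extent[1] | df$x > extent[2] |
          df$y < extent[3] | df$y > extent[4]))
    stop("points fall outside the declared extent")
  structure(df, extent = extent, class = c("r2r_points", "data.frame"))
}
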
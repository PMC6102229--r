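# Shared 3x3 finite-difference terrain operators (Horn 1981 gradients).
# Edge cells use replicated borders so outputs cover the full grid.

pad_replicate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr + 2L, nc + 2L)
  out[2:(nr + 1), 2:(nc + 1)] <- m
  out[1, ] <- out[2, ]; out[nr + 2, ] <- out[nr + 1, ]
  out[, 1] <- out[, 2]; out[, nc + 2] <- out[, nc + 1]
  out
}

shift_mat <- function(p, dr, dc, nr, nc) {
  p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
}

# Horn gradients dz/dx (east+) and dz/dy (north+) in z-units per meter.
# NA cells are locally patched with the center value so coastal fringes keep
# a defined slope; cells that are themselves NA stay NA.
horn_gradient <- function(m, cell_size) {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_replicate(m)
  z <- list()
  ks <- list(nw = c(-1, -1), n = c(-1, 0), ne = c(-1, 1),
             w = c(0, -1), c = c(0, 0), e = c(0, 1),
             sw = c(1, -1), s = c(1, 0), se = c(1, 1))
  ctr <- shift_mat(p, 0, 0, nr, nc)
  for (k in names(ks)) {
    v <- shift_mat(p, ks[[k]][1], ks[[k]][2], nr, nc)
    v[is.na(v)] <- ctr[is.na(v)]
    z[[k]] <- v
  }
  dzdx <- ((z$ne + 2 * z$e + z$se) - (z$nw + 2 * z$w + z$sw)) / (8 * cell_size)
  dzdy <- ((z$nw + 2 * z$n + z$ne) - (z$sw + 2 * z$s + z$se)) / (8 * cell_size)
  dzdx[is.na(ctr)] <- NA; dzdy[is.na(ctr)] <- NA
  list(dzdx = dzdx, dzdy = dzdy)
}

# Slope as rise/run (m/m) and as degrees.
horn_slope <- function(m, cell_size) {
  g <- horn_gradient(m, cell_size)
  tan_s <- sqrt(g$dzdx^2 + g$dzdy^2)
  list(tan = tan_s, deg = atan(tan_s) * 180 / pi,
       dzdx = g$dzdx, dzdy = g$dzdy)
}

# Aspect: steepest downslope direction, degrees clockwise from north.
# Downslope vector is -grad z with components (east, north) = (-dzdx, -dzdy).
# Flat cells (zero gradient) return NA.
horn_aspect <- function(m, cell_size) {
  g <- horn_gradient(m, cell_size)
  asp <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  asp[abs(g$dzdx) < 1e-12 & abs(g$dzdy) < 1e-12] <- NA
  asp
}

# Moving-window mean with a circular kernel of given radius (in cells).
# Shrinks at edges and around NA cells (mean over available cells).
focal_circle_mean <- function(m, radius_cells) {
  r <- max(1L, as.integer(floor(radius_cells)))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2 + 1e-9, ]
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    src_r <- rs - dr; src_c <- cs - dc
    v <- m[src_r, src_c, drop = FALSE]
    ok <- !is.na(v)
    v[!ok] <- 0
    s[rs, cs] <- s[rs, cs] + v
    n[rs, cs] <- n[rs, cs] + ok
  }
  out <- s / n
  out[n == 0] <- NA
  out
}
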
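# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's C++ primitives.

# D8 direction offsets matching the package convention (E,SE,S,SW,W,NW,N,NE).
.dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
.dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
.dl <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# Follow the D8 path from (r, c); returns the list of visited (r, c) pairs
# (including the start), stopping before leaving the grid / entering NA.
oracle_path <- function(fd, r, c) {
  path <- list()
  repeat {
    path[[length(path) + 1]] <- c(r, c)
    d <- fd[r, c]
    if (is.na(d) || d < 0) break
    rn <- r + .dr[d + 1]; cn <- c + .dc[d + 1]
    if (rn < 1 || rn > nrow(fd) || cn < 1 || cn > ncol(fd) ||
        is.na(fd[rn, cn])) break
    r <- rn; c <- cn
  }
  path
}

# Upslope set of a cell: all cells whose path passes through it.
oracle_upslope <- function(fd, r0, c0) {
  hits <- list()
  for (r in seq_len(nrow(fd))) for (c in seq_len(ncol(fd))) {
    if (is.na(fd[r, c])) next
    p <- oracle_path(fd, r, c)
    if (any(vapply(p, function(q) q[1] == r0 && q[2] == c0, logical(1))))
      hits[[length(hits) + 1]] <- c(r, c)
  }
  hits
}

# Horn slope (m/m), written directly from the 3x3 kernel definition with
# replicated borders.
oracle_horn_slope <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  gv <- function(r, c) {
    r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
    v <- z[r, c]
    v
  }
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    g <- function(dr, dc) {
      v <- gv(r + dr, c + dc)
      if (is.na(v)) z[r, c] else v
    }
    dzdx <- ((g(-1, 1) + 2 * g(0, 1) + g(1, 1)) -
               (g(-1, -1) + 2 * g(0, -1) + g(1, -1))) / (8 * cs)
    dzdy <- ((g(-1, -1) + 2 * g(-1, 0) + g(-1, 1)) -
               (g(1, -1) + 2 * g(1, 0) + g(1, 1))) / (8 * cs)
    out[r, c] <- sqrt(dzdx^2 + dzdy^2)
  }
  out
}

# Brute-force Borselli connectivity index (same contract as
# compute_connectivity: slope floored at 0.005, C floored at 0.001, D_up =
# Cbar*Sbar*sqrt(A) over upslope incl. self, D_dn = sum of step/(C*S) down
# to the first stream cell, stream cells NA).
oracle_ic <- function(dem, Cg, fd, stream, cs) {
  S <- pmax(oracle_horn_slope(dem, cs), 0.005)
  Cw <- pmax(Cg, 0.001)
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dem[r, c]) || isTRUE(stream[r, c] > 0)) next
    up <- oracle_upslope(fd, r, c)
    n <- length(up)
    cbar <- mean(vapply(up, function(q) Cw[q[1], q[2]], numeric(1)))
    sbar <- mean(vapply(up, function(q) S[q[1], q[2]], numeric(1)))
    d_up <- cbar * sbar * sqrt(n * cs^2)
    # walk down to the first stream cell
    p <- oracle_path(fd, r, c)
    d_dn <- NA_real_
    acc <- 0
    found <- FALSE
    for (i in seq_along(p)) {
      q <- p[[i]]
      if (isTRUE(stream[q[1], q[2]] > 0)) { found <- TRUE; break }
      d <- fd[q[1], q[2]]
      if (is.na(d) || d < 0) break
      step <- .dl[d + 1] * cs
      acc <- acc + step / (Cw[q[1], q[2]] * S[q[1], q[2]])
      # check whether the next cell exists (path may end off-grid)
      if (i == length(p)) break
    }
    if (found) d_dn <- acc
    out[r, c] <- if (is.na(d_dn)) NA_real_ else log10(d_up / d_dn)
  }
  out
}

# O(V^2) Dijkstra over the 8-neighborhood with mean-cost edges.
oracle_dijkstra <- function(u, cs, r0, c0) {
  nr <- nrow(u); nc <- ncol(u)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[r0, c0] <- 0
  repeat {
    best <- Inf; br <- 0; bc <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc))
      if (!done[r, c] && !is.na(u[r, c]) && dist[r, c] < best) {
        best <- dist[r, c]; br <- r; bc <- c
      }
    if (!is.finite(best)) break
    done[br, bc] <- TRUE
    for (k in 1:8) {
      r <- br + .dr[k]; c <- bc + .dc[k]
      if (r < 1 || r > nr || c < 1 || c > nc || is.na(u[r, c])) next
      nd <- best + .dl[k] * cs * (u[br, bc] + u[r, c]) / 2
      if (nd < dist[r, c]) dist[r, c] <- nd
    }
  }
  dist[is.infinite(dist)] <- NA
  dist[is.na(u)] <- NA
  dist
}

# Exhaustive minimal prefix search for the linkage rule: the smallest subset
# of watersheds whose summed contribution exceeds threshold * total, checked
# against all subsets.
oracle_min_subset <- function(contrib, threshold) {
  total <- sum(contrib)
  n <- length(contrib)
  best_size <- Inf; best <- NULL
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (sum(contrib[sel]) > threshold * total && length(sel) < best_size) {
      best_size <- length(sel)
      best <- sel
    }
  }
  best_size
}
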
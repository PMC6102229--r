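test_that("geography: depth sign declared, shore distance Euclidean", {
  n <- 9
  bathy <- r2r_grid(matrix(5, n, n), 60)
  bathy$values[, 1] <- NA  # land column
  coast <- grid_like(bathy, matrix(0, n, n))
  coast$values[, 1] <- 1
  expect_error(compute_geography(bathy, coast), "declared")
  geo <- compute_geography(bathy, coast, "positive_down")
  expect_true(all(is.na(geo$depth$values[, 1])) ||
                all(geo$depth$values[, 1] >= 0, na.rm = TRUE))
  expect_true(all(is.na(geo$dist_shore$values[, 1])))  # land cells nodata
  # 5 cells due east of the shore column -> 5 * 60 = 300 m
  expect_equal(geo$dist_shore$values[5, 6], 300)
  expect_equal(geo$dist_shore$values[5, 1 + 1], 60)
  # negative-down convention flips sign
  bneg <- bathy; bneg$values <- -bathy$values
  geo2 <- compute_geography(bneg, coast, "negative_down")
  expect_equal(geo2$depth$values[3, 3], 5)
})

test_that("BPI is zero on flats, positive on pinnacles, negative in channels", {
  flat <- r2r_grid(matrix(10, 9, 9), 60)
  expect_true(all(abs(compute_bpi(flat, 120)$values) < 1e-12))
  pin <- r2r_grid(matrix(20, 9, 9), 60)
  pin$values[5, 5] <- 4    # shallow pinnacle
  bpi <- compute_bpi(pin, 120)
  expect_gt(bpi$values[5, 5], 0)
  chan <- r2r_grid(matrix(5, 9, 9), 60)
  chan$values[5, ] <- 15   # deep channel
  expect_lt(compute_bpi(chan, 120)$values[5, 5], 0)
  expect_error(compute_bpi(flat, 10), "radius")
})

test_that("terrain: planes have exact slope and zero curvature; bowls match analytics", {
  n <- 11; cs <- 60
  # plane dipping 10 degrees to the east (depth increases east)
  drop <- tan(10 * pi / 180) * cs
  plane <- r2r_grid(matrix(rep((0:(n - 1)) * drop, each = n), n, n), cs)
  terr <- compute_terrain(plane)
  inner <- terr$slope$values[3:(n - 2), 3:(n - 2)]
  expect_equal(inner, matrix(10, n - 4, n - 4), tolerance = 1e-9)
  expect_true(all(abs(terr$curv_plan$values[3:(n - 2), 3:(n - 2)]) < 1e-9))
  expect_true(all(abs(terr$curv_prof$values[3:(n - 2), 3:(n - 2)]) < 1e-9))
  flat <- compute_terrain(r2r_grid(matrix(3, n, n), cs))
  expect_true(all(flat$slope$values == 0))
  expect_true(all(flat$curv_prof$values == 0))
  # bowl z = x^2 + y^2 (in km to keep slopes moderate): profile curvature
  # positive and equal to z''/(1+z'^2)^1.5 along an axis
  xs <- ((1:n) - (n + 1) / 2) * cs
  bowl_elev <- outer(xs, xs, function(y, x) (x / 1000)^2 + (y / 1000)^2) * 1000
  bowl <- r2r_grid(-bowl_elev, cs)   # stored as depth (positive down)
  terr2 <- compute_terrain(bowl)
  r0 <- (n + 1) / 2
  x1 <- xs[8] / 1000
  zp <- 2 * x1; zpp <- 2
  k_analytic <- zpp / (1 + zp^2)^1.5 / 1000  # per meter
  expect_gt(terr2$curv_prof$values[r0, 8], 0)
  expect_equal(terr2$curv_prof$values[r0, 8], k_analytic, tolerance = 0.02)
})

test_that("exposure: aspect and circular statistics behave on planes", {
  n <- 9; cs <- 60
  # seafloor dipping due north: depth decreases northward?? -- downslope of
  # the surface (elevation -depth) toward north means depth grows north.
  north_deep <- r2r_grid(matrix(seq(20, 4, length.out = n), n, n), cs)
  # rows 1..n run north -> south with depth 20 -> 4: deeper north
  ex <- compute_exposure(north_deep)
  expect_equal(ex$aspect$values[5, 5], 0, tolerance = 1e-9)
  expect_equal(ex$northness$values[5, 5], 1, tolerance = 1e-9)
  expect_equal(ex$eastness$values[5, 5], 0, tolerance = 1e-9)
  east_deep <- r2r_grid(matrix(rep(seq(4, 20, length.out = n), each = n),
                               n, n), cs)
  ex2 <- compute_exposure(east_deep)
  expect_equal(ex2$eastness$values[5, 5], 1, tolerance = 1e-9)
  expect_equal(abs(ex2$northness$values[5, 5]), 0, tolerance = 1e-9)
  # uniform aspect field -> circular SD 0
  expect_true(all(ex$aspect_circ_sd$values[2:8, 2:8] < 1e-6))
  expect_error(compute_exposure(north_deep, window = 4), "window")
})

test_that("habitat metrics: contiguity, fractal dimension, Shannon", {
  m <- matrix(1, 7, 7)
  m[4, 4] <- 2  # single-cell patch
  hab <- r2r_grid(m, 60)
  hm <- compute_habitat_metrics(hab, window_m = 180, search_radius_m = 400)
  expect_equal(hm$contiguity$values[4, 4], 0)
  expect_true(all(hm$contiguity$values >= 0 & hm$contiguity$values <= 1,
                  na.rm = TRUE))
  expect_true(all(hm$fractal_dim$values >= 1 - 1e-9 &
                    hm$fractal_dim$values <= 2 + 1e-9, na.rm = TRUE))
  # one-class window -> shannon 0; two equal classes -> ln 2
  one <- compute_habitat_metrics(r2r_grid(matrix(3, 6, 6), 60), 180, 400)
  expect_true(all(one$shannon$values == 0))
  half <- matrix(1, 6, 6); half[, 4:6] <- 2
  hs <- compute_habitat_metrics(r2r_grid(half, 60), window_m = 700,
                                search_radius_m = 400)
  # window wide enough to always hold both classes equally at the seam
  expect_equal(hs$shannon$values[3, 3], log(2), tolerance = 0.15)
  expect_error(compute_habitat_metrics(
    r2r_grid(matrix(NA_real_, 4, 4), 60)), "empty")
})

test_that("driver operators are translation-invariant in the interior", {
  set.seed(5)
  z <- matrix(cumsum(rnorm(144, 0, 0.3)), 12, 12) + 10
  g1 <- r2r_grid(z, 60)
  z2 <- rbind(z[11:12, ], z[1:10, ])   # shift south by two rows
  g2 <- r2r_grid(z2, 60)
  t1 <- compute_terrain(g1)$slope$values
  t2 <- compute_terrain(g2)$slope$values
  expect_equal(t1[2:8, 2:10], t2[4:10, 2:10], tolerance = 1e-12)
  b1 <- compute_bpi(g1, 120)$values
  b2 <- compute_bpi(g2, 120)$values
  expect_equal(b1[4:8, 4:8], b2[6:10, 4:8], tolerance = 1e-12)
})
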
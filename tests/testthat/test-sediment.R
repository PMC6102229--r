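test_that("Bols erosivity matches its closed form", {
  g <- function(p) r2r_grid(matrix(p, 2, 2), 30)
  expect_equal(compute_erosivity(g(0))$values[1, 1], 0)
  expect_equal(compute_erosivity(g(100))$values[1, 1], 25000 / 803,
               tolerance = 1e-12)
  expect_equal(compute_erosivity(g(10))$values[1, 1], 250 / 146,
               tolerance = 1e-12)
  # monotone increasing for P > 0
  p <- seq(1, 500, by = 7)
  r <- vapply(p, function(x) compute_erosivity(g(x))$values[1, 1], numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(compute_erosivity(g(-5)), "negative")
  # monthly sum vs annual evaluation differ (convexity)
  months <- lapply(rep(100, 12), g)
  expect_gt(compute_erosivity(months, "annual")$values[1, 1],
            compute_erosivity(months, "monthly")$values[1, 1])
})

test_that("fill_and_route on an inclined plane drains downslope", {
  g <- plane_grid(6)
  rt <- fill_and_route(g)
  fd <- rt$flow_dir$values
  # interior cells flow east (code 0)
  expect_true(all(fd[2:5, 1:5] == 0))
  # accumulation grows along the fall line
  acc <- rt$flow_accum$values
  expect_true(all(diff(acc[3, ]) > 0))
  expect_equal(acc[3, 1], 1)
})

test_that("single pits are filled to their pour elevation", {
  z <- matrix(5, 5, 5)
  z[3, 3] <- 1          # pit
  z[3, 4:5] <- 4        # spill corridor to the edge at elevation 4
  g <- r2r_grid(z, 30)
  rt <- fill_and_route(g)
  expect_gte(rt$filled$values[3, 3], 4)
  expect_lt(rt$filled$values[3, 3], 4.01)
  expect_error(fill_and_route(r2r_grid(matrix(2, 4, 4), 30)), "flat")
})

test_that("3x3 cone: center accumulates only itself, outlet is maximal", {
  z <- matrix(1, 3, 3); z[2, 2] <- 5
  z[1, ] <- c(0.9, 0.8, 0.9)  # slight tilt so the outlet is unique
  rt <- fill_and_route(r2r_grid(z, 30))
  acc <- rt$flow_accum$values
  expect_equal(acc[2, 2], 1)
  expect_equal(max(acc), acc[1, 2])
})

test_that("stream delineation thresholds accumulation", {
  g <- plane_grid(5)
  rt <- fill_and_route(g)
  expect_true(all(delineate_streams(rt$flow_accum, 1)$values == 1))
  big <- max(rt$flow_accum$values) + 1
  expect_true(all(delineate_streams(rt$flow_accum, big)$values == 0))
})

test_that("watershed labels partition land and respect symmetry", {
  # two symmetric valleys on a ridge: west half drains west, east half east
  n <- 8
  z <- outer(rep(1, n), c(1, 2, 3, 4, 4, 3, 2, 1)) * 10
  g <- r2r_grid(z, 30)
  rt <- fill_and_route(g)
  ctr <- grid_centers(g)
  pp <- data.frame(id = c(1, 2),
                   x = c(ctr$x[1], ctr$x[n]),
                   y = c(ctr$y[4], ctr$y[4]))
  ws <- delineate_watersheds(rt$flow_dir, pp)
  lab <- ws$labels$values
  expect_true(all(lab %in% c(0, 1, 2)))
  expect_equal(sum(lab == 1), sum(lab == 2))
  expect_error(delineate_watersheds(rt$flow_dir, rbind(pp, pp[1, ])),
               "duplicate")
  # one pour point draining a whole bowl -> one label everywhere
  zb <- outer((1:6 - 3.5)^2, (1:6 - 3.5)^2, `+`) + 10
  zb[6, 3] <- 0.1
  gb <- r2r_grid(zb, 30)
  rtb <- fill_and_route(gb)
  ctb <- grid_centers(gb)
  wsb <- delineate_watersheds(rtb$flow_dir,
                              data.frame(id = 9, x = ctb$x[3], y = ctb$y[6]))
  expect_true(all(wsb$labels$values == 9))
})

test_that("LS factor is ~0 on flats and monotone in slope and area", {
  flat <- r2r_grid(matrix(3, 5, 5), 30)
  acc1 <- r2r_grid(matrix(1, 5, 5), 30)
  expect_true(all(compute_ls(flat, acc1)$values < 0.05))
  # monotone in contributing area at fixed slope (inclined plane)
  g <- plane_grid(6, drop_per_cell = 3)
  for (a in list(1, 5, 20, 100)) {
    ls_a <- compute_ls(g, r2r_grid(matrix(a, 6, 6), 30))$values[3, 3]
    ls_b <- compute_ls(g, r2r_grid(matrix(a + 1, 6, 6), 30))$values[3, 3]
    expect_gte(ls_b, ls_a)
  }
  # monotone in slope at fixed area
  ls_by_slope <- vapply(c(1, 2, 4, 8), function(d) {
    gg <- plane_grid(6, drop_per_cell = d)
    compute_ls(gg, r2r_grid(matrix(10, 6, 6), 30))$values[3, 3]
  }, numeric(1))
  expect_true(all(diff(ls_by_slope) > 0))
})

test_that("RUSLE multiplies factors and cell area", {
  mk <- function(x) r2r_grid(matrix(x, 3, 3), 30)
  f <- list(R = mk(100), K = mk(0.002), LS = mk(1), C = mk(0.1))
  loss <- compute_rusle(f, cell_area_ha = 0.09)
  expect_equal(loss$values[1, 1], 100 * 0.002 * 1 * 0.1 * 0.09)
  expect_equal(loss$values[2, 2], 0.0018)
  f0 <- f; f0$R <- mk(0)
  expect_true(all(compute_rusle(f0, 0.09)$values == 0))
  f2 <- f; f2$C <- mk(0.2)
  expect_equal(compute_rusle(f2, 0.09)$values, 2 * loss$values)
  # K nodata filled with the fallback erodibility
  fk <- f; fk$K$values[1, 1] <- NA
  lk <- compute_rusle(fk, 0.09, k_fill = 0.002)
  expect_equal(lk$values[1, 1], loss$values[1, 1])
})

test_that("SDR logistic hits its midpoint and asymptotes", {
  prm <- sdr_params()
  ic <- r2r_grid(matrix(c(0.5, 1e6, -1e6, 0.5), 2, 2), 30)
  sdr <- compute_sdr(ic, prm)
  expect_equal(sdr$values[1, 1], 0.4, tolerance = 1e-12)
  expect_equal(sdr$values[2, 1], 0.8, tolerance = 1e-12)
  expect_equal(sdr$values[1, 2], 0, tolerance = 1e-12)
})

test_that("connectivity and export match the brute-force oracle on small grids", {
  set.seed(11)
  for (n in c(5, 8)) {
    z <- outer(seq(n * 2, 2, length.out = n), seq(3, 0, length.out = n), `+`) +
      matrix(runif(n * n, 0, 0.4), n, n)
    dem <- r2r_grid(z, 30)
    rt <- fill_and_route(dem)
    Cg <- r2r_grid(matrix(runif(n * n, 0.01, 0.6), n, n), 30)
    streams <- delineate_streams(rt$flow_accum, max(3, n - 2))
    ic <- compute_connectivity(rt$filled, Cg, rt$flow_dir, streams)
    ora <- oracle_ic(rt$filled$values, Cg$values, rt$flow_dir$values,
                     streams$values, 30)
    expect_equal(ic$values, ora, tolerance = 1e-9)
    # export equivalence: soil loss x SDR, watershed sums conserve mass
    sdr <- compute_sdr(ic)
    loss <- r2r_grid(matrix(runif(n * n, 0, 5), n, n), 30)
    ctr <- grid_centers(dem)
    best <- which(rt$flow_accum$values == max(rt$flow_accum$values),
                  arr.ind = TRUE)[1, ]
    ws <- delineate_watersheds(rt$flow_dir,
                               data.frame(id = 1, x = ctr$x[best[2]],
                                          y = ctr$y[best[1]]))
    res <- compute_export(loss, sdr, ws)
    manual <- loss$values * sdr$values
    manual[is.na(sdr$values)] <- 0
    expect_equal(res$export$values, manual, tolerance = 1e-9)
    lab <- ws$labels$values
    expect_equal(res$watershed_loads$load_t_yr,
                 sum(manual[lab == 1]), tolerance = 1e-9)
  }
})

test_that("export respects the SDR bound and linearity", {
  ch <- fixture_chain()
  res <- ch$sediment$result
  loss <- ch$sediment$soil_loss
  expect_lte(res$total_t_yr, 0.8 * sum(loss$values, na.rm = TRUE) + 1e-9)
  expect_true(all(res$export$values <= loss$values + 1e-9, na.rm = TRUE))
  # partition conservation: watershed loads sum to export over labeled cells
  lab <- ch$sediment$watersheds$labels$values
  labeled <- sum(res$export$values[lab > 0 & !is.na(lab)], na.rm = TRUE)
  expect_equal(sum(res$watershed_loads$load_t_yr), labeled, tolerance = 1e-9)
})

test_that("raising C never decreases watershed loads (scenario monotonicity)", {
  b <- fixture_island()
  C1 <- c_factor_grid(b$land_cover)
  # replace native forest C by the (larger) monoculture C
  cf2 <- default_c_factors()
  cf2["native_forest"] <- cf2["taro_monoculture"]
  C2 <- c_factor_grid(b$land_cover, cf2)
  st1 <- sediment_stage(b$dem, b$rain, b$K, C1, b$pour_points)
  st2 <- sediment_stage(b$dem, b$rain, b$K, C2, b$pour_points)
  m <- merge(st1$result$watershed_loads, st2$result$watershed_loads,
             by = "watershed_id")
  expect_true(all(m$load_t_yr.y >= m$load_t_yr.x - 1e-9))
})
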
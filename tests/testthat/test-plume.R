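mkg <- function(v, n = 5, cs = 60) r2r_grid(matrix(v, n, n), cs)

test_that("cost surface composites normalized drivers", {
  depth <- mkg(seq(0, 24, length.out = 25))
  dist <- mkg(seq(0, 2400, length.out = 25))
  wind <- mkg(seq(0, 180, length.out = 25))
  # all weight on distance -> cost proportional to normalized distance
  p_dist <- plume_params(0, 1, 0)
  cst <- build_cost_surface(depth, dist, wind, p_dist)
  nd <- (dist$values - min(dist$values)) / diff(range(dist$values))
  expect_equal(cst$values, pmax(nd, p_dist$cost_floor), tolerance = 1e-12)
  # uniform drivers -> uniform floor cost, with a warning per constant grid
  expect_warning(u <- build_cost_surface(mkg(5), mkg(7), mkg(1),
                                         plume_params()), "constant")
  expect_true(all(u$values == plume_params()$cost_floor))
  # deeper, more exposed cell costs more than shallow sheltered at equal dist
  d2 <- mkg(c(2, rep(1, 24))); d2$values[2, 2] <- 20
  w2 <- mkg(c(10, rep(10, 24))); w2$values[2, 2] <- 170
  cst2 <- build_cost_surface(d2, mkg(rep(c(0, 1000), length.out = 25)), w2,
                             plume_params())
  expect_gt(cst2$values[2, 2], cst2$values[4, 4])
})

test_that("accumulated cost matches Dijkstra brute force (with a wall)", {
  set.seed(3)
  u <- matrix(runif(25, 0.2, 1), 5, 5)
  u[, 3] <- 50      # high-cost wall
  u[5, 3] <- 0.2    # gap at the south: path must route around
  g <- r2r_grid(u, 60)
  cd <- accumulate_cost(g, c(30, 270))  # cell (1,1) center
  ora <- oracle_dijkstra(u, 60, 1, 1)
  expect_equal(cd$values, ora, tolerance = 1e-9)
  expect_equal(cd$values[1, 1], 0)
  # uniform cost: one orthogonal step = u * cell_size
  gu <- r2r_grid(matrix(0.5, 4, 4), 60)
  cu <- accumulate_cost(gu, c(30, 210))
  expect_equal(cu$values[1, 2], 0.5 * 60, tolerance = 1e-12)
  expect_equal(cu$values[2, 2], 0.5 * 60 * sqrt(2), tolerance = 1e-12)
  # disconnected cells -> NA
  ud <- matrix(1, 3, 3); ud[, 2] <- NA
  cdd <- accumulate_cost(r2r_grid(ud, 60), c(30, 90))
  expect_true(all(is.na(cdd$values[, 3])))
})

test_that("dispersal decay follows S = s_p exp(-c^2/D_c) with a 3 km cutoff", {
  cost <- mkg(c(0, 1, 2, 3, rep(4, 21)))
  shore <- mkg(100)
  prm <- plume_params(d_c = 4)
  s <- disperse(10, cost, prm, shore)
  expect_equal(s$values[1, 1], 10)                     # c = 0
  expect_equal(s$values[3, 1], 10 / exp(1))            # c^2 = D_c (c = 2)
  # zero beyond 3 km from shore
  shore2 <- mkg(100); shore2$values[5, 5] <- 3100
  s2 <- disperse(10, cost, prm, shore2)
  expect_equal(s2$values[5, 5], 0)
  # linear in s_p
  expect_equal(disperse(20, cost, prm, shore)$values, 2 * s$values)
  expect_error(disperse(-1, cost, prm, shore), "s_p")
})

test_that("monotone decay along increasing-cost paths and plume bound", {
  ch <- fixture_chain()
  pl <- ch$plume
  for (wid in names(pl$plumes)) {
    p <- pl$plumes[[wid]]
    expect_true(all(p$values <= pl$s_p[[wid]] + 1e-9, na.rm = TRUE))
    cost <- pl$cost[[wid]]
    ok <- !is.na(cost$values) & !is.na(p$values) & p$values > 0
    # along any increasing-cost ordering, S is non-increasing
    ordr <- order(cost$values[ok])
    expect_true(all(diff(p$values[ok][ordr]) <= 1e-9))
  }
})

test_that("sum_plumes adds fields cellwise and retains components", {
  a <- mkg(0); a$values[1, 1] <- 5
  b <- mkg(0); b$values[5, 5] <- 3
  sp <- sum_plumes(list(w1 = a, w2 = b))
  expect_equal(sp$tss$values[1, 1], 5)
  expect_equal(sp$tss$values[5, 5], 3)
  expect_equal(sum(sp$tss$values), 8)
  one <- sum_plumes(list(w1 = a))
  expect_equal(one$tss$values, a$values)
  # contribution fractions sum to 1 wherever tss > 0
  ch <- fixture_chain()
  tss <- ch$plume$tss$values
  fr <- Reduce(`+`, lapply(ch$plume$plumes, function(p)
    ifelse(tss > 0, p$values / tss, 0)))
  expect_true(all(abs(fr[tss > 0 & !is.na(tss)] - 1) < 1e-9))
})
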
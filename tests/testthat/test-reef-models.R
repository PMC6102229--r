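make_tab <- function(n = 150, seed = 1, noise = 0.01,
                     fun = function(x) 2 * x[, 1]) {
  set.seed(seed)
  X <- matrix(runif(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  df <- as.data.frame(X)
  df$response <- fun(X) + rnorm(n, 0, noise)
  df$x <- runif(n, 0, 1000); df$y <- runif(n, 0, 1000)
  model_table(df, c("a", "b", "c"))
}

test_that("correlation filter drops the right predictors", {
  set.seed(2)
  df <- data.frame(a = rnorm(80))
  df$b <- df$a                                   # identical twin
  df$c <- rnorm(80)
  df$response <- rnorm(80)
  tab <- model_table(df, c("a", "b", "c"))
  expect_equal(sort(filter_correlated(tab)), c("a", "c"))
  # all pairwise below threshold -> nothing dropped
  df2 <- data.frame(a = rnorm(200), c = rnorm(200), response = 0)
  df2$b <- 0.3 * df2$a + sqrt(1 - 0.09) * rnorm(200)
  tab2 <- model_table(df2, c("a", "b", "c"))
  expect_setequal(filter_correlated(tab2), c("a", "b", "c"))
  # chain r(A,B)=.9, r(B,C)=.9, r(A,C)~.6: B has the largest mean |r|
  set.seed(4)
  a <- rnorm(4000); cc <- rnorm(4000)
  bmid <- (a + cc) / sqrt(2) * 0.95 + rnorm(4000, 0, sqrt(1 - 0.95^2))
  df3 <- data.frame(a = a, b = bmid, c = cc, response = 0)
  tab3 <- model_table(df3, c("a", "b", "c"))
  expect_setequal(filter_correlated(tab3, r_max = 0.6), c("a", "c"))
  expect_error(filter_correlated(model_table(
    data.frame(a = 1:5, response = 0), "a")), "2 predictors")
})

test_that("BRT recovers a single noiseless driver with matching curve", {
  tab <- make_tab(n = 200, noise = 0.001)
  m <- fit_brt(tab, fast_brt())
  expect_gt(m$influence[["a"]], 90)
  expect_equal(sum(m$influence), 100, tolerance = 0.01)
  curve_a <- m$curves[m$curves$predictor == "a", ]
  expect_gt(cor(curve_a$x, curve_a$partial), 0.99)
  expect_gt(m$pde, 0.9)
  expect_gt(m$cv_pde, 0.9)
  # determinism under a fixed seed
  m2 <- fit_brt(tab, fast_brt())
  expect_identical(predict(m, tab), predict(m2, tab))
  expect_identical(m$influence, m2$influence)
})

test_that("constant responses yield a degenerate null model", {
  tab <- make_tab(fun = function(x) rep(3, nrow(x)), noise = 0)
  m <- fit_brt(tab, fast_brt())
  expect_equal(m$pde, 0)
  expect_true(m$degenerate)
  tabbad <- make_tab()
  tabbad$response[3] <- NaN
  expect_error(fit_brt(tabbad, fast_brt()), "non-finite")
})

test_that("BRT models survive a JSON round trip", {
  dir <- withr::local_tempdir()
  tab <- make_tab(n = 120)
  m <- fit_brt(tab, fast_brt())
  p <- file.path(dir, "m.json")
  write_brt(m, p)
  m2 <- read_brt(p)
  expect_equal(predict(m2, tab), predict(m, tab), tolerance = 1e-12)
  expect_equal(m2$cv_pde, m$cv_pde, tolerance = 1e-12)
})

test_that("Moran's I flags clustered residuals and accepts iid ones", {
  # value = x coordinate: perfectly clustered
  set.seed(9)
  n <- 60
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  df$x <- runif(n, 0, 100); df$y <- runif(n, 0, 100)
  df$response <- df$x / 10
  tab <- model_table(df, c("a", "b", "c"))
  m <- list(fitted = rep(mean(tab$response), n))
  mi <- moran_residuals(m, tab)
  expect_gt(mi$observed, 0.2)
  expect_lt(mi$p_value, 0.01)
  # iid residuals: I near -1/(n-1) on average, p mostly insignificant
  set.seed(10)
  obs <- replicate(20, {
    df$response <- rnorm(n)
    moran_residuals(list(fitted = rep(0, n)), model_table(df, c("a", "b", "c")))$observed
  })
  expect_lt(abs(mean(obs) - (-1 / (n - 1))), 0.03)
  # degenerate inputs
  df2 <- df[1:2, ]
  expect_error(moran_residuals(list(fitted = c(0, 0)),
                               model_table(df2, c("a", "b", "c"))), "10 points")
  df$x[2] <- df$x[1]; df$y[2] <- df$y[1]
  df$response <- rnorm(n)
  expect_error(moran_residuals(list(fitted = rep(0, n)),
                               model_table(df, c("a", "b", "c"))),
               "coincident")
})

test_that("sample_predictors interpolates bilinearly and drops nodata rows", {
  g <- r2r_grid(matrix(c(0, 0, 1, 1), 2, 2), 10)
  gna <- r2r_grid(matrix(c(NA, 2, 2, 2), 2, 2), 10)
  sv <- r2r_points(data.frame(x = c(5, 10), y = c(15, 10),
                              cover = c(25, 16)))
  tab <- sample_predictors(list(p1 = g), sv, "cover", "sqrt")
  expect_equal(tab$p1, c(0, 0.5))
  expect_equal(tab$response, c(5, 4))
  # two of 21 points touch the nodata cell (9.5% dropped: warn, not error)
  expect_warning(
    tab2 <- sample_predictors(list(p1 = g, p2 = gna),
                              r2r_points(data.frame(
                                x = c(5, 10, rep(15, 19)),
                                y = c(15, 10, rep(5, 19)),
                                cover = 1:21)), "cover", "sqrt"),
    "dropped")
  expect_equal(nrow(tab2), 19)
  # a majority-dropped table signals misaligned inputs
  expect_error(suppressWarnings(sample_predictors(
    list(p1 = g, p2 = gna),
    r2r_points(data.frame(x = c(5, 10, 15), y = c(15, 10, 5),
               cover = 1:3)), "cover", "sqrt")), "misaligned")
})

test_that("hierarchy: benthos-driven fish recover their benthic driver", {
  ch <- fixture_chain()
  stack <- ch$stack[setdiff(names(ch$stack), "aspect")]
  stack$tss <- ch$plume$tss
  b <- ch$bundle
  b$tss <- ch$plume$tss
  sv <- make_reef_surveys(b, n_sites = 150, noise_sd = 0.2, seed = 5)
  # fish response built synthetically from coral cover only; the benthic
  # columns are replaced by mutually independent fields so the correlation
  # filter cannot merge coral with its covarying benthic neighbors
  set.seed(6)
  sv$cca <- runif(nrow(sv), 0, 30)
  sv$macroalgae <- runif(nrow(sv), 0, 30)
  sv$turf <- runif(nrow(sv), 0, 30)
  sv$coral <- runif(nrow(sv), 0, 60)
  sv$fishy <- pmax(1 + 0.1 * sqrt(sv$coral), 0)^4
  benthic <- c("cca", "coral", "macroalgae", "turf")
  btabs <- suppressWarnings(lapply(benthic, function(i)
    sample_predictors(stack, sv, i, "sqrt")))
  names(btabs) <- benthic
  ftab <- suppressWarnings(sample_predictors(
    stack["depth"], sv, "fishy", "fourth_root", extra_predictors = benthic))
  hier <- fit_hierarchy(btabs, list(fishy = ftab), fast_brt())
  expect_length(hier$benthic, 4)
  m <- hier$fish$fishy
  expect_equal(names(sort(m$influence, decreasing = TRUE))[1], "coral")
  # a fish table without the benthic columns is rejected
  bad <- suppressWarnings(sample_predictors(stack["depth"], sv, "fishy",
                                            "fourth_root"))
  expect_error(fit_hierarchy(btabs, list(fishy = bad), fast_brt()),
               "lacks benthic")
})

test_that("prediction maps honor domain, transform and clipping", {
  ch <- fixture_chain()
  stack <- ch$stack[setdiff(names(ch$stack), "aspect")]
  stack$tss <- ch$plume$tss
  b <- ch$bundle; b$tss <- ch$plume$tss
  sv <- make_reef_surveys(b, n_sites = 120, noise_sd = 0.5, seed = 8)
  tab <- suppressWarnings(sample_predictors(stack, sv, "coral", "sqrt"))
  keep <- filter_correlated(tab)
  m <- fit_brt(ridge2reef:::retain_predictors(tab, keep), fast_brt())
  mp <- predict_map(m, stack, max_depth_m = 22)
  deep <- !is.na(stack$depth$values) & stack$depth$values > 22
  expect_true(all(is.na(mp$values[deep])))
  ok <- !is.na(mp$values)
  expect_true(all(mp$values[ok] >= 0 & mp$values[ok] <= 100))
  ev <- evaluate_predictions(mp, sv, "coral")
  expect_gt(ev$r_squared, 0.2)
  expect_lt(ev$p_value, 0.01)
  # observed == predicted -> R^2 = 1; constant map -> R^2 = 0
  svp <- sv
  svp$self <- grid_sample(mp, sv$x, sv$y)
  svp <- svp[is.finite(svp$self), ]
  expect_equal(evaluate_predictions(mp, svp, "self")$r_squared, 1,
               tolerance = 1e-9)
  const <- grid_like(mp, matrix(5, nrow(mp$values), ncol(mp$values)))
  expect_warning(ev0 <- evaluate_predictions(const, svp, "self"),
                 "zero-variance")
  expect_equal(ev0$r_squared, 0)
  expect_error(predict_map(m, stack["depth"]), "lacks predictor")
})
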
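#' Boosted-regression-tree tuning configuration
#'
#' Candidate hyperparameter grids for Gaussian BRT calibration with internal
#' k-fold cross-validation: learning rate (shrinkage), tree complexity
#' (number of splits per tree), bag fraction (subsample share per tree), and
#' a tree-count ceiling. The optimal tree count per combination is the
#' cross-validated deviance minimizer; the optimal combination maximizes CV
#' percent deviance explained.
#'
#' @param lr_grid candidate learning rates.
#' @param tc_grid candidate tree complexities (splits per tree).
#' @param bag_grid candidate bag fractions in (0, 1].
#' @param max_trees ceiling on boosting iterations.
#' @param folds number of CV folds (>= 2).
#' @param min_obs minimum observations per terminal node.
#' @param seed RNG seed used for fold assignment and bagging.
#' @return list of class `brt_config`.
#' @export
brt_config <- function(lr_grid = c(0.01, 0.005, 0.001),
                       tc_grid = c(1, 2, 3, 5),
                       bag_grid = c(0.5, 0.75),
                       max_trees = 10000, folds = 10, min_obs = 5,
                       seed = 1L) {
  stopifnot(folds >= 2, all(bag_grid > 0), all(bag_grid <= 1),
            all(lr_grid > 0), all(tc_grid >= 1), max_trees >= 1)
  structure(list(lr_grid = lr_grid, tc_grid = tc_grid, bag_grid = bag_grid,
                 max_trees = as.integer(max_trees), folds = as.integer(folds),
                 min_obs = as.integer(min_obs), seed = as.integer(seed)),
            class = "brt_config")
}

transform_response <- function(x, transform = c("sqrt", "fourth_root")) {
  transform <- match.arg(transform)
  if (any(x < 0, na.rm = TRUE)) stop("response must be nonnegative")
  if (transform == "sqrt") sqrt(x) else x^0.25
}

back_transform <- function(x, transform = c("sqrt", "fourth_root")) {
  transform <- match.arg(transform)
  x <- pmax(x, 0)
  if (transform == "sqrt") x^2 else x^4
}

#' Fit a tuned boosted-regression-tree model for one reef indicator
#'
#' Runs the full calibration: for every (lr, tc, bag) combination the
#' boosting path is grown stagewise on each CV fold, the tree count
#' minimizing the summed held-out deviance is chosen, and the combination
#' with the highest CV percent deviance explained wins (ties broken toward
#' smaller tree complexity, then smaller learning rate). The winning
#' combination is refit on all rows at the selected tree count; relative
#' influence (percent, summing to 100) and per-predictor partial-dependence
#' curves (100 quantile-spaced points) are computed on that refit.
#'
#' @param table a `model_table` (see [model_table]) whose `response` column
#'   is already on the transformed scale.
#' @param config [brt_config].
#' @return object of class `brt_model` with elements `pde`, `cv_pde`,
#'   `influence` (named percents), `curves` (data frame), `best` (chosen
#'   hyperparameters), `n_trees`, and the tree ensemble.
#' @export
fit_brt <- function(table, config = brt_config()) {
  stopifnot(inherits(table, "model_table"))
  preds <- attr(table, "predictors")
  y <- table$response
  if (any(!is.finite(y))) stop("non-finite response values")
  X <- as.matrix(table[, preds, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 5 * config$folds)
    stop("need at least ", 5 * config$folds, " rows for ", config$folds,
         "-fold calibration")
  set.seed(config$seed)
  fold <- sample(rep(seq_len(config$folds), length.out = n))
  ss0 <- sum((y - mean(y))^2)
  degenerate <- ss0 < 1e-12
  combos <- expand.grid(bag = sort(config$bag_grid),
                        lr = sort(config$lr_grid),
                        tc = sort(config$tc_grid))
  combos <- combos[order(combos$tc, combos$lr, combos$bag), ]
  best <- NULL
  if (!degenerate) {
    for (i in seq_len(nrow(combos))) {
      set.seed(config$seed + 1000L)
      cv <- cpp_boost_cv(X, y, as.integer(fold), combos$lr[i],
                         as.integer(combos$tc[i]), combos$bag[i],
                         config$max_trees, config$min_obs)
      m <- which.min(cv$cv_sse)
      cv_pde <- 1 - cv$cv_sse[m] / cv$null_sse
      if (is.null(best) || cv_pde > best$cv_pde + 1e-12) {
        best <- list(lr = combos$lr[i], tc = combos$tc[i],
                     bag = combos$bag[i], n_trees = m, cv_pde = cv_pde)
      }
    }
  }
  if (is.null(best))
    best <- list(lr = combos$lr[1], tc = combos$tc[1], bag = combos$bag[1],
                 n_trees = 1L, cv_pde = 0)
  set.seed(config$seed + 2000L)
  fit <- cpp_boost_fit(X, y, best$lr, as.integer(best$tc), best$bag,
                       as.integer(best$n_trees), config$min_obs)
  sse <- sum((y - fit$fitted)^2)
  pde <- if (degenerate) 0 else max(0, 1 - sse / ss0)
  gains <- fit$gains
  if (sum(gains) <= 0) {
    influence <- rep(100 / length(preds), length(preds))
    degenerate <- TRUE
  } else influence <- 100 * gains / sum(gains)
  names(influence) <- preds
  curves <- do.call(rbind, lapply(seq_along(preds), function(j) {
    xs <- unique(quantile(X[, j], probs = seq(0.005, 0.995, length.out = 100),
                          names = FALSE))
    ys <- cpp_boost_pd(fit$init, fit$var, fit$split, fit$left, fit$right,
                       fit$value, fit$offset, fit$n_trees, X, j - 1L, xs)
    data.frame(predictor = preds[j], x = xs, partial = ys)
  }))
  structure(list(
    ensemble = fit[c("init", "var", "split", "left", "right", "value",
                     "offset", "n_trees")],
    best = best[c("lr", "tc", "bag")], n_trees = best$n_trees,
    pde = pde, cv_pde = max(0, best$cv_pde), influence = influence,
    curves = curves, predictors = preds,
    response = attr(table, "response_name"),
    transform = attr(table, "transform"),
    fitted = fit$fitted, degenerate = degenerate,
    table_digest = sum(abs(y)) + sum(abs(X))
  ), class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("<brt_model> %s (%s): lr=%g tc=%d bag=%g trees=%d\n",
              x$response, x$transform, x$best$lr, x$best$tc, x$best$bag,
              x$n_trees))
  cat(sprintf("  PDE %.1f%%, CV PDE %.1f%%\n", 100 * x$pde, 100 * x$cv_pde))
  top <- sort(x$influence, decreasing = TRUE)[1:min(5, length(x$influence))]
  cat("  top influence:",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted BRT on the transformed scale
#' @param object a `brt_model`.
#' @param newdata data frame or matrix containing the model's predictors.
#' @param ... unused.
#' @return numeric predictions (transformed scale).
#' @export
predict.brt_model <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss))
    stop("missing predictors: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  e <- object$ensemble
  cpp_boost_predict(e$init, e$var, e$split, e$left, e$right, e$value,
                    e$offset, e$n_trees, X)
}

#' Serialize / restore a fitted BRT model as JSON
#' @param model a `brt_model`.
#' @param path output file.
#' @export
write_brt <- function(model, path) {
  obj <- unclass(model)
  obj$curves <- as.list(obj$curves)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_brt
#' @export
read_brt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$curves <- as.data.frame(obj$curves)
  obj$influence <- stats::setNames(as.numeric(obj$influence), obj$predictors)
  e <- obj$ensemble
  obj$ensemble <- list(init = e$init, var = as.integer(e$var),
                       split = as.numeric(e$split), left = as.integer(e$left),
                       right = as.integer(e$right),
                       value = as.numeric(e$value),
                       offset = as.integer(e$offset),
                       n_trees = as.integer(e$n_trees))
  structure(obj, class = "brt_model")
}
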
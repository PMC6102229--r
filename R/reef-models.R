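#' Build a model table from driver grids and reef surveys
#'
#' Samples every predictor grid at the survey coordinates (bilinear for
#' continuous grids, nearest-neighbor for class-coded grids named in
#' `class_predictors`), attaches the response on the transformed scale
#' (square root for benthic % cover, fourth root for fish biomass), and
#' drops rows with any missing predictor (with a warning; more than 10%
#' dropped signals misaligned inputs and is an error).
#'
#' @param stack named list of driver grids (may include the `tss` grid).
#' @param surveys an [r2r_points] table containing the response column.
#' @param response name of the response column in `surveys`.
#' @param transform `"sqrt"` (benthic) or `"fourth_root"` (fish).
#' @param extra_predictors optional data-frame columns of `surveys` to use
#'   as additional predictors (e.g. observed benthic covers for fish
#'   models).
#' @param class_predictors names of stack entries holding class codes.
#' @return data frame of class `model_table` with attributes `predictors`,
#'   `response_name`, `transform`, and the survey coordinates.
#' @export
sample_predictors <- function(stack, surveys, response,
                              transform = c("sqrt", "fourth_root"),
                              extra_predictors = character(),
                              class_predictors = character()) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(surveys))
  vals <- lapply(names(stack), function(nm) {
    method <- if (nm %in% class_predictors) "nearest" else "bilinear"
    grid_sample(stack[[nm]], surveys$x, surveys$y, method)
  })
  names(vals) <- names(stack)
  tab <- as.data.frame(vals)
  for (ep in extra_predictors) tab[[ep]] <- surveys[[ep]]
  tab$response <- transform_response(surveys[[response]], transform)
  tab$x <- surveys$x; tab$y <- surveys$y
  preds <- c(names(stack), extra_predictors)
  keep <- stats::complete.cases(tab[, c(preds, "response")])
  if (any(!keep)) {
    warning(sum(!keep), " survey rows dropped (nodata neighborhood)")
    if (mean(!keep) > 0.10)
      stop("more than 10% of survey rows dropped: misaligned inputs?")
  }
  tab <- tab[keep, , drop = FALSE]
  structure(tab, predictors = preds, response_name = response,
            transform = transform,
            class = c("model_table", "data.frame"))
}

#' Constructor for a model table from a plain data frame
#' @param df data frame containing predictors and `response` (transformed).
#' @param predictors predictor column names.
#' @param response_name label for the modeled indicator.
#' @param transform transform tag.
#' @export
model_table <- function(df, predictors, response_name = "response",
                        transform = "sqrt") {
  stopifnot(all(predictors %in% names(df)), "response" %in% names(df))
  structure(as.data.frame(df), predictors = predictors,
            response_name = response_name, transform = transform,
            class = c("model_table", "data.frame"))
}

#' Drop highly correlated predictors
#'
#' Greedy filter: while any predictor pair has |Pearson r| > `r_max`, take
#' the most correlated pair and drop the member with the larger mean
#' absolute correlation to all remaining predictors (ties drop the
#' later-ordered column). Deterministic.
#'
#' @param table a `model_table` (or data frame with a `predictors`
#'   attribute).
#' @param r_max correlation threshold (default 0.7).
#' @return character vector of retained predictor names.
#' @export
filter_correlated <- function(table, r_max = 0.7) {
  preds <- attr(table, "predictors")
  if (length(preds) < 2) stop("need at least 2 predictors")
  keep <- preds
  repeat {
    cm <- abs(stats::cor(as.data.frame(table)[, keep, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(cm)
    drop_idx <- if (mean_abs[ij[1]] > mean_abs[ij[2]] + 1e-12) ij[1]
    else if (mean_abs[ij[2]] > mean_abs[ij[1]] + 1e-12) ij[2]
    else max(ij)
    keep <- keep[-drop_idx]
    if (length(keep) < 2) stop("fewer than 2 predictors survive the filter")
  }
  keep
}

# Restrict a model table to a subset of predictors.
retain_predictors <- function(table, keep) {
  structure(table, predictors = keep,
            response_name = attr(table, "response_name"),
            transform = attr(table, "transform"),
            class = class(table))
}

#' Moran's I on model residuals
#'
#' Inverse-distance weights (row-standardized), normal-approximation
#' p-value; the null expectation is -1/(n-1).
#'
#' @param model a fitted `brt_model`.
#' @param table the `model_table` the model was fit on.
#' @param coords optional 2-column matrix of coordinates (defaults to the
#'   table's `x`/`y` columns).
#' @return list with `observed`, `expected`, `sd`, `p_value`.
#' @export
moran_residuals <- function(model, table, coords = NULL) {
  if (is.null(coords)) coords <- cbind(table$x, table$y)
  res <- table$response - model$fitted
  n <- length(res)
  if (n < 10) stop("need at least 10 points for Moran's I")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] < 1e-9))
    stop("coincident coordinates collapse the weight matrix")
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  mi <- ape::Moran.I(res, w)
  list(observed = mi$observed, expected = mi$expected, sd = mi$sd,
       p_value = mi$p.value)
}

#' Fit the benthic-then-fish model hierarchy
#'
#' All benthic indicator models are fit first; each fish model then includes
#' the observed benthic covers among its predictors (at prediction time the
#' fish models consume the predicted benthic maps instead).
#'
#' @param benthic_tables named list of `model_table`s (one per benthic
#'   indicator).
#' @param fish_tables named list of `model_table`s whose predictors include
#'   the benthic indicator columns.
#' @param config [brt_config].
#' @param r_max correlation filter threshold applied per table.
#' @return list of class `reef_model_set` with `benthic` and `fish` model
#'   lists and the retained predictor sets.
#' @export
fit_hierarchy <- function(benthic_tables, fish_tables,
                          config = brt_config(), r_max = 0.7) {
  fit_one <- function(tab) {
    keep <- filter_correlated(tab, r_max)
    fit_brt(retain_predictors(tab, keep), config)
  }
  benthic <- lapply(benthic_tables, fit_one)
  benthic_names <- names(benthic_tables)
  fish <- lapply(fish_tables, function(tab) {
    miss <- setdiff(benthic_names, attr(tab, "predictors"))
    if (length(miss))
      stop("fish table lacks benthic predictors: ",
           paste(miss, collapse = ", "))
    fit_one(tab)
  })
  structure(list(benthic = benthic, fish = fish,
                 benthic_names = benthic_names),
            class = "reef_model_set")
}

#' Predict a 60 m indicator map from a fitted model
#'
#' Evaluates the ensemble cell by cell over the reef model domain (marine
#' cells no deeper than `max_depth_m`), inverts the response transform, and
#' clips to the indicator's valid range (benthic 0-100% cover, fish >= 0).
#'
#' @param model a `brt_model`.
#' @param stack named list of driver grids; must cover every model
#'   predictor. Include predicted benthic maps here for fish models.
#' @param max_depth_m prediction-domain depth limit (m, default 22, the
#'   maximum surveyed depth).
#' @param domain optional logical matrix further restricting the domain.
#' @return prediction grid.
#' @export
predict_map <- function(model, stack, max_depth_m = 22, domain = NULL) {
  miss <- setdiff(model$predictors, names(stack))
  if (length(miss))
    stop("stack lacks predictor grids: ", paste(miss, collapse = ", "))
  depth <- stack$depth
  stopifnot(!is.null(depth))
  ok <- !is.na(depth$values) & depth$values <= max_depth_m
  if (!is.null(domain)) ok <- ok & domain
  for (nm in model$predictors)
    ok <- ok & !is.na(stack[[nm]]$values)
  idx <- which(ok)
  X <- vapply(model$predictors, function(nm) stack[[nm]]$values[idx],
              numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1)
  colnames(X) <- model$predictors
  pred_t <- predict(model, X)
  pred <- back_transform(pred_t, model$transform)
  if (model$transform == "sqrt") pred <- pmin(pred, 100)
  out <- matrix(NA_real_, nrow(depth$values), ncol(depth$values))
  out[idx] <- pred
  grid_like(depth, out)
}

#' Regress observed survey values on map predictions
#'
#' Bilinearly samples the prediction map at the survey points and fits
#' ordinary least squares observed ~ predicted.
#'
#' @param predicted prediction grid from [predict_map].
#' @param surveys [r2r_points] with the observed indicator column.
#' @param response observed column name.
#' @return list with `r_squared`, `p_value` (slope test), `n`.
#' @export
evaluate_predictions <- function(predicted, surveys, response) {
  pred <- grid_sample(predicted, surveys$x, surveys$y, "bilinear")
  obs <- surveys[[response]]
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(pred) < 10) stop("need at least 10 survey points inside the map")
  if (sd(pred) < 1e-12) {
    # a constant map explains nothing; flagged rather than fatal so scenario
    # sweeps do not abort on a degenerate indicator
    warning("zero-variance predictions")
    return(list(r_squared = 0, p_value = NA_real_, n = length(pred)))
  }
  fit <- lm(obs ~ pred)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["pred", "Pr(>|t|)"],
       n = length(pred))
}
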
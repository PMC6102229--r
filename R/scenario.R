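# Land-cover class codes used across the pipeline. The C-factor lookup is a
# literature-default table keyed by class name; it is user-overridable via
# the pipeline configuration (the study's own supplementary values are not
# reproduced here).
LAND_CLASSES <- c(native_forest = 1, secondary_forest = 2, shrubland = 3,
                  pine_plantation = 4, taro_monoculture = 5,
                  kava_monoculture = 6, bare = 7)

#' Default cover-management (C) factors by land-cover class
#'
#' Literature defaults for humid tropical covers: dense native forest near
#' 0.003, managed pine plantation 0.05, root-crop monoculture ~0.3.
#' @return named numeric vector, values in \[0, 1\].
#' @export
default_c_factors <- function() {
  c(native_forest = 0.003, secondary_forest = 0.008, shrubland = 0.015,
    pine_plantation = 0.05, taro_monoculture = 0.35, kava_monoculture = 0.30,
    bare = 0.50)
}

#' Rebuild the C-factor grid from a land-cover class grid
#' @param land_use class-code grid (codes of `LAND_CLASSES`).
#' @param c_factors named vector keyed by class name.
#' @return C-factor grid.
#' @export
c_factor_grid <- function(land_use, c_factors = default_c_factors()) {
  lut <- rep(NA_real_, max(LAND_CLASSES))
  lut[LAND_CLASSES[names(c_factors)]] <- c_factors
  v <- land_use$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  codes <- v[ok]
  if (any(!(codes %in% LAND_CLASSES)))
    stop("unknown land-cover class code(s): ",
         paste(unique(codes[!(codes %in% LAND_CLASSES)]), collapse = ", "))
  out[ok] <- lut[codes]
  grid_like(land_use, out)
}

#' Scenario specification
#'
#' @param land_use `"current"`, `"deforestation"`, or `"restoration"`.
#' @param bleaching `"none"`, `"low"`, `"moderate"`, or `"high"`.
#' @param bleaching_mode `"proportional"` (multiplicative reduction,
#'   default) or `"absolute"` (percentage-point subtraction).
#' @return list of class `scenario_spec`. The depth-stratified coral-cover
#'   reductions are: low = 10% at < 5 m; moderate = 30% at < 5 m; high =
#'   30% at 0-5 m and 10% at 5-10 m; deeper cells unchanged.
#' @export
scenario_spec <- function(land_use = c("current", "deforestation",
                                       "restoration"),
                          bleaching = c("none", "low", "moderate", "high"),
                          bleaching_mode = c("proportional", "absolute")) {
  land_use <- match.arg(land_use)
  bleaching <- match.arg(bleaching)
  bleaching_mode <- match.arg(bleaching_mode)
  reductions <- switch(bleaching,
    none = data.frame(depth_min = numeric(), depth_max = numeric(),
                      reduction = numeric()),
    low = data.frame(depth_min = 0, depth_max = 5, reduction = 0.10),
    moderate = data.frame(depth_min = 0, depth_max = 5, reduction = 0.30),
    high = data.frame(depth_min = c(0, 5), depth_max = c(5, 10),
                      reduction = c(0.30, 0.10)))
  structure(list(land_use = land_use, bleaching = bleaching,
                 bleaching_mode = bleaching_mode, reductions = reductions),
            class = "scenario_spec")
}

#' Apply a land-use change scenario
#'
#' Deforestation: inside logging concessions, forestry-suitable land (land
#' use capability classes V-VII) converts to pine plantation; outside
#' concessions, arable land (LUC I-IV) under convertible cover (native or
#' secondary forest, shrubland) converts to taro monoculture. Conservation
#' land (LUC VIII) is never converted. Restoration: existing pine
#' plantations revert to native forest. Current: identity. The C-factor
#' grid is rebuilt from the resulting classes.
#'
#' @param land_use class-code grid.
#' @param luc land-use-capability class grid (integer I-VIII as 1-8).
#' @param concessions logging-concession mask grid (1 = inside).
#' @param spec [scenario_spec].
#' @param c_factors C-factor lookup passed to [c_factor_grid].
#' @return list with `land_use` (new class grid), `C` (rebuilt C-factor
#'   grid), and `ledger` (per-class area before/after, ha).
#' @export
apply_landuse_scenario <- function(land_use, luc, concessions, spec,
                                   c_factors = default_c_factors()) {
  grid_check_aligned(land_use, luc); grid_check_aligned(land_use, concessions)
  lv <- land_use$values
  if (any(!(lv[!is.na(lv)] %in% LAND_CLASSES)))
    stop("unknown land-cover class code")
  lucv <- luc$values
  if (any(!(lucv[!is.na(lucv)] %in% 1:8)))
    stop("LUC classes must be I-VIII (coded 1-8)")
  before <- lv
  conc <- !is.na(concessions$values) & concessions$values > 0
  convertible <- lv %in% LAND_CLASSES[c("native_forest", "secondary_forest",
                                        "shrubland")]
  if (spec$land_use == "deforestation") {
    to_pine <- conc & lucv %in% 5:7 & convertible
    to_mono <- !conc & lucv %in% 1:4 & convertible
    lv[to_pine] <- LAND_CLASSES[["pine_plantation"]]
    lv[to_mono] <- LAND_CLASSES[["taro_monoculture"]]
  } else if (spec$land_use == "restoration") {
    lv[lv == LAND_CLASSES[["pine_plantation"]] & !is.na(lv)] <-
      LAND_CLASSES[["native_forest"]]
  }
  cell_ha <- land_use$cell_size^2 / 1e4
  cls <- LAND_CLASSES
  ledger <- data.frame(
    class = names(cls),
    area_ha_before = vapply(cls, function(k)
      sum(before == k, na.rm = TRUE) * cell_ha, numeric(1)),
    area_ha_after = vapply(cls, function(k)
      sum(lv == k, na.rm = TRUE) * cell_ha, numeric(1)))
  new_lu <- grid_like(land_use, lv)
  list(land_use = new_lu, C = c_factor_grid(new_lu, c_factors),
       ledger = ledger)
}

#' Apply a depth-stratified bleaching scenario to a coral-cover map
#'
#' In each depth band the predicted coral cover is reduced by the band's
#' rate: proportionally (cover * (1 - r), default) or by absolute
#' percentage points (cover - 100 r), clipped at 0.
#'
#' @param coral_map predicted coral % cover grid.
#' @param depth depth grid (m), aligned.
#' @param spec [scenario_spec].
#' @return adjusted coral map.
#' @export
apply_bleaching <- function(coral_map, depth, spec) {
  if (is.null(depth)) stop("missing depth grid")
  grid_check_aligned(coral_map, depth)
  v <- coral_map$values
  red <- spec$reductions
  for (i in seq_len(nrow(red))) {
    band <- !is.na(depth$values) & depth$values >= red$depth_min[i] &
      depth$values < red$depth_max[i] & !is.na(v)
    if (spec$bleaching_mode == "proportional")
      v[band] <- v[band] * (1 - red$reduction[i])
    else v[band] <- pmax(v[band] - 100 * red$reduction[i], 0)
  }
  grid_like(coral_map, v)
}
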
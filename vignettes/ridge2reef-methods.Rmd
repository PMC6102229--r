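---
title: "ridge2reef: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ridge2reef: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models it
implements, the parameters that matter (with units, defaults and why), what
the synthetic-data generator does and does not emulate, the numerical
choices, and the limitations a user should keep in mind. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The linked land–sea framework

The pipeline treats a tropical high island as a chain of one-way physical
and statistical couplings:

land cover + rain + soil + terrain → hillslope erosion → delivery to pour
points → coastal dispersal (TSS proxy) → reef indicator models → scenario
differences → land prioritization.

All land computations run on a 30 m grid and all marine computations on a
60 m grid; the only land→sea handoff is the per-watershed load at its
shoreline pour point. This keeps the resolutions of the two domains honest
(no mixed-resolution algebra) and makes the watershed the natural
management unit. Coordinates are projected meters, rows run north→south,
and cell centers carry cell values.

## 2. Hillslope erosion (RUSLE)

Per-cell soil loss is `R · K · LS · C · P × cell area`:

* **R**, rainfall erosivity (MJ·mm·ha⁻¹·hr⁻¹), from the Bols empirical
  relation `R = 2.5 P² / (100 (0.073 P + 0.73))`. The default applies the
  relation to each monthly precipitation grid and sums; an `annual` mode
  applies it once to the annual total. The source method's aggregation is
  ambiguous ("derived from monthly rainfall averages"), so both modes are
  exposed (`erosivity_mode`); monthly is the default because erosivity is
  convex in P and monthly aggregation is the common practice for the Bols
  family of relations.
* **K**, soil erodibility (ton·ha·hr·MJ⁻¹·ha⁻¹·mm⁻¹), an input grid.
  Missing K cells are filled with 0.002, the same fallback the reference
  calibration used for unmapped soils.
* **LS** uses the Desmet–Govers contributing-area form with the McCool
  slope factor, the aspect-corrected unit-contour width `x = |sin α| +
  |cos α|`, and contributing area measured at the cell inlet
  (`(accumulation − 1) × cell²`). LS is capped at `333·tan(θ)^0.83`
  (optionally a fixed ceiling), which both bounds extreme convergence
  values and sends genuinely flat cells to ≈ 0.
* **C** comes from a per-class lookup. The shipped defaults are literature
  values for humid tropical covers (native forest 0.003, secondary forest
  0.008, shrubland 0.015, pine plantation 0.05, kava 0.30, taro 0.35, bare
  0.50); the study's own supplementary table was not available, so the
  table is deliberately user-overridable (`c_factors` config key).
* **P** (management practice) is fixed at 1 — the source model excluded it
  for lack of data, and so does this package.

## 3. Routing, connectivity, and delivery

Depressions are filled by priority-flood with a tiny (1e-7 m) increment,
which guarantees every land cell a strictly descending D8 path to the
coast; flow directions are steepest-descent D8 and accumulation counts
include the cell itself. D8 (single direction) was chosen because the
downslope term of the connectivity index is defined along *the* flow path;
multiple-flow-direction routing (used by some reference implementations)
would spread both area and path sums and produce small numeric differences
on real data — a documented deviation, not a bug.

The Borselli connectivity index is `IC = log₁₀(D_up / D_dn)` with
`D_up = C̄ · S̄ · √A` over the upslope area (means include the cell) and
`D_dn = Σ dᵢ/(Cᵢ Sᵢ)` along the path to the first stream cell (`dᵢ` is the
step length through cell *i*: 30 m orthogonal, 30·√2 m diagonal). Slope is
Horn slope floored at 0.005 m/m and C is floored at 0.001 in the weights —
standard guards against division by zero on flats and bare-rock C = 0.
Streams are accumulation ≥ `flow_accum_threshold` (default 50 cells ≈
4.5 ha at 30 m, a typical channel-initiation threshold for volcanic
terrain; it is a config key). Stream cells are excluded from IC; their
delivery is implicit in the export of the cells draining to them. Cells
with no path to a stream (tiny coastal fringes) export nothing.

`SDR = SDR_max / (1 + exp((IC₀ − IC)/k))` with the published calibration
IC₀ = 0.5, k = 2.0, SDR_max = 0.8 — at IC = IC₀ the ratio is exactly 0.4.
Export = soil loss × SDR; watershed loads are label sums, with watersheds
delineated by following every cell's D8 path to labeled shoreline pour
points.

## 4. Coastal plume dispersal

Each pour point's load spreads over an accumulated least-cost surface
(8-connected Dijkstra; edge cost = planimetric step × mean unit cost of the
two cells). The per-cell unit cost is a weighted sum of min-max-normalized
depth, distance to the stream mouth, and wind exposure. The source method
names these three drivers but not the functional form; equal weights
(⅓, ⅓, ⅓) are this package's choice and are config keys. A constant driver
(e.g. uniform wind) is warned about and contributes zero. Costs are floored
at 1e-3 so travel is never free.

Dispersal is `S = s_p · exp(−c²/D_c)`, zero beyond 3 km from the shoreline.
`D_c` is defined in the source only as "equivalent to 3 km from the
shoreline"; here it is auto-calibrated per pour point as the mean
accumulated cost over marine cells 2,700–3,300 m from shore (falling back
to the band around the farthest reachable distance on domains smaller than
3 km), so the decay scale is commensurate with the cutoff by construction.
Dispersal is purely diffusive — no advection, tides, or settling — which
matches the source's stated scope and makes plumes conservative wrap-around
fields rather than directional ones.

## 5. Marine drivers

From bathymetry (depth positive down — the sign convention must be declared
in the geography step): depth; Euclidean distance to the coastline (exact
distance transform); BPI at 60 m and 240 m radii, computed on elevation
(−depth) so ridges are positive — the convention of the benthic terrain
modeling literature; Horn slope (degrees); slope-of-slope (the same
operator applied to the slope grid); planar and profile curvature from the
local quadratic fit, signed so a bowl is positive; aspect (steepest
downslope azimuth, flat cells NA) with windowed circular mean converted to
northness/eastness and circular SD `√(−2 ln R̄)` (default 3×3 window — the
source's window is unstated; it is a config key).

From the habitat class map: 4-connected patches (conservative
fragmentation; 8-connected available) carry FRAGSTATS-style contiguity
(orthogonal weight 2, diagonal 1, rescaled to [0, 1]; a lone cell scores
0), perimeter–area fractal dimension `2 ln(0.25 P)/ln A` (exactly 1 for a
square cell, ≤ 2 otherwise), and proximity `Σ area/d²` over same-class
patches within a 500 m search radius. Shannon diversity (−Σ p ln p, natural
log, i.e. nats) of class proportions uses a 270 m moving window. Edge cells
use shrunken windows rather than NA so narrow fringing-reef strips stay in
the model table.

## 6. Reef indicator models

Benthic indicators (CCA, coral, macroalgae, turf; % cover) are modeled on
the square-root scale, fish biomasses (browsers, grazers, scrapers,
predators; kg·ha⁻¹) on the fourth-root scale, with Gaussian gradient
boosting of shallow regression trees. Predictors are sampled at survey
coordinates by bilinear interpolation (nearest-neighbor for class grids); a
row with any missing predictor is dropped with a warning, and dropping more
than 10% of rows aborts, since that pattern indicates misaligned inputs.
Predictor pairs with |Pearson r| > 0.7 are thinned greedily: the member of
the most correlated pair with the larger mean absolute correlation is
removed first — so of a chain A–B–C, the middle proxy B goes.

The boosting engine is implemented in compiled code within the package
(the classic gbm-style machinery: per-tree bag-fraction subsampling, tc
splits grown best-first, leaf means shrunk by the learning rate). The
calibration mirrors the stepwise cross-validation practice of the boosted
regression tree literature: for each (lr, tc, bag) candidate, the boosting
path is grown on each of ten folds and the tree count minimizing the summed
held-out deviance is selected; the candidate with the highest
cross-validated percent deviance explained (CV PDE = 1 − held-out
SSE/held-out null SSE) wins, with ties broken toward smaller tree
complexity then smaller learning rate (parsimony). Defaults follow the
published parameter roster (lr ∈ {0.01, 0.005, 0.001}, tc ∈ {1, 2, 3, 5},
bag ∈ {0.5, 0.75}, ≤ 10,000 trees, 10 folds; the candidate values
themselves are unreported in the source and are this artifact's defaults).
The pipeline and test runs use a reduced grid and tree ceiling purely for
compute budget; that is a runtime scaling, not a change of defaults.

Relative influence is the split-gain share per predictor (sums to 100%);
response curves are partial dependence evaluated at 100 quantile-spaced
points by brute-force averaging over the training rows. Spatial
autocorrelation of residuals is tested with Moran's I under row-standardized
inverse-distance weights (normal approximation; null expectation
−1/(n−1)), delegated to `ape::Moran.I`.

Fish models are hierarchical: fit on *observed* benthic covers as extra
predictors, and at prediction time fed the *predicted* (and, under
bleaching, adjusted) benthic maps. Predictions are made per cell over reef
cells no deeper than 22 m (the maximum surveyed depth), back-transformed
(square or fourth power after clamping at zero) and clipped to valid ranges
(0–100% cover; ≥ 0 kg·ha⁻¹). Map quality is summarized by OLS of observed
on predicted at the survey points (R², slope p); a zero-variance prediction
map yields R² = 0 with a warning rather than an abort, so scenario sweeps
survive a degenerate indicator.

## 7. Scenarios

Land-use rules operate on land-use-capability (LUC) classes I–VIII:
deforestation converts forestry-suitable classes V–VII inside logging
concessions to pine plantation and arable classes I–IV outside concessions
to taro monoculture; conservation-class VIII cells never convert; and only
"convertible" covers (native forest, secondary forest, shrubland) convert —
water, bare and existing agriculture do not (the source is silent on this
boundary; forest-and-shrubland is the reading adopted). Restoration
converts pine plantation back to native forest and nothing else. The
C-factor grid is rebuilt from the resulting classes, so scenarios change C
only at reclassified cells.

Bleaching reduces predicted coral cover in depth bands: low = 10% at
< 5 m; moderate = 30% at < 5 m; high = 30% at 0–5 m plus 10% at 5–10 m;
deeper cells are untouched. "Reduced by 10%" is read as a proportional
(multiplicative) reduction — consistent with the percent-decline
projections the scenarios were derived from; an absolute
percentage-point mode is available behind `bleaching_mode = "absolute"`.

## 8. Impact assessment and prioritization

Scenario minus present differences are classified per cell against the
domain-wide empirical difference distribution:
`p = Φ((d − μ_d)/σ_d)`, significant when p falls in either α/2 tail
(α = 0.10 two-sided — the source's α is assumed two-tailed; a rank-based
mode using the empirical CDF is provided for clearly non-Gaussian
fields). Identical maps (σ_d = 0) flag nothing. Summaries use 0.36 ha per
60 m cell; fish totals are Σ(Δ kg·ha⁻¹ × 0.36)/1000 tonnes. Where sediment
and bleaching footprints overlap, their changes are summed (additivity
assumption, flagged as areas of potential interaction rather than a modeled
interaction).

Linkage sums each watershed's retained plume over the significant reef
cells and takes the smallest descending-contribution prefix exceeding 90%
of the total — an aggregate reading of "the majority (>90%) of the total
load at those areas". Priority land areas: in climate mode, the smallest
top-export cell set per linked watershed exceeding 66% of that watershed's
export (ties broken by higher flow accumulation, then row-major order, for
deterministic outputs — the cumulative-set reading of the >66% rule was
adopted over a per-cell percentile reading); in land-use mode, the cells of
linked watersheds whose export change is significant at α = 0.10. Priority
masks are buffered by 100 m using an exact Euclidean distance transform on
a 10 m subgrid and polygonized by boundary tracing; a lone 30 m cell yields
a rounded square of area `a² + 4ar + πr²` ≈ 4.43 ha to within the subgrid
discretization (~2%), and nearby buffers merge.

## 9. The synthetic island: the stated world

`make_island(seed, n_cells)` builds a deterministic bundle at 30 m (land)
and 60 m (sea): a 420 m volcanic cone whose inter-valley ridges and
incised radial valleys (default 4) force ≥ 95% of land cells to drain
through the valley pour points — a low coastal berm, broken only at the
valley mouths, routes near-shore drainage alongshore exactly as beach
ridges do on real volcanic coasts, and all valley/berm length scales are
proportional to the island radius so the drainage geometry is
size-invariant. Ground-truth watershed labels are the azimuthal valley
sectors, defined by construction geometry and *not* by any flow routing, so
the ≥ 95% delineation-agreement test is a genuine cross-check of the
router. Land cover is predominantly native forest with seeded shrubland and
secondary-forest patches, coastal pine plantations concentrated in one
quadrant (so restoration has somewhere to act), and small lowland
taro/kava monocultures; LUC classes follow slope bands; a concession wedge
covers two valleys. Monthly rainfall is seasonal (≈ 100–280 mm/month) with
0.35 mm per meter of orographic lift; K is ≈ 0.015 with smooth spatial
noise and a few deliberate nodata holes to exercise the K fallback.

Offshore, depth grows at 12 m/km from a 0.5 m reef flat, with a barrier
ridge shoaling to ~3 m at 700 m offshore; habitat classes partition reef
flat / lagoon / crest / fore slope / deep; wind exposure is highest on the
south-east (trade-wind) sector.

Surveys (`make_reef_surveys`, default n = 163, the size of the field
campaign the framework was calibrated on) are stratified over the three
survey depth bins (0.5–2, 5–8, 12–15 m). Benthic responses are sums of
monotone logistic terms in standardized TSS, depth, slope and complexity on
the square-root scale — the matching model family, so parameter recovery is
a fair test — with signs fixed to the calibrated directions (sediment
negative on CCA, coral, turf, grazers and predators; depth positive on
CCA/coral and negative on macroalgae/turf). Fish responses are linear in
the standardized transformed benthos plus terrain and sediment terms on
the fourth-root scale. Noise is Gaussian on the transformed scale with SD
equal to `noise_sd` × the deterministic signal SD; the default
`noise_sd = 1` (signal-to-noise 1:1, transformed-scale R² ≈ 0.5) was chosen
once as the calibration that places cross-validated deviance in the
reported 12–50.5% CV PDE range, and the acceptance suite asserts exactly
that. When the pipeline has produced its own TSS grid it drives the
sediment effect in the surveys; before that, an analytic plume field from
the construction geometry stands in.

What a green test does establish: the estimators recover the signs and
rough ranking of known monotone effects from data generated by the matching
model family at realistic noise, through the package's own TSS field. What
it does not establish: performance under real-world complications the
generator deliberately omits — survey measurement structure (transects,
observers), non-monotone or interacting driver effects, advective plumes,
gully/landslip erosion, or habitat maps with classification error.

## 10. Numerical choices and degenerate inputs

* Depression filling uses ε = 1e-7 m increments; flats therefore acquire a
  deterministic drainage direction toward their spill.
* All-flat DEMs, empty habitat maps, negative precipitation, negative
  noise, undeclared depth sign, duplicate pour-point cells, < 100 cells in
  a significance test, and < 10 points for Moran's I are hard errors.
* Constant responses fit a degenerate null BRT (PDE 0, uniform influence,
  flagged) rather than erroring, and constant prediction maps evaluate to
  R² = 0 with a warning.
* Ranking ties anywhere in prioritization are broken deterministically
  (flow accumulation, then row-major order); hyperparameter ties by
  parsimony. Two runs with one seed are byte-identical.
* Serialization keeps float32 round-trips bit-exact (17 significant digits
  in the ASCII writer).

## 11. Limitations

Nutrient runoff, gully/landslip/streambank erosion, in-stream deposition,
advective and tidal transport, coral adaptation dynamics, and economic
analysis are out of scope, mirroring the source framework's stated
boundaries. Reproducing the Fiji case-study export totals requires the
study's data deposit and a reference SDR implementation whose flow routing
(possibly multiple-flow-direction) differs from this package's D8 choice;
differences within a few percent should be expected on real terrain. The
CRS is carried as an opaque tag — no reprojection is performed, and all
inputs must share a projected metric CRS.
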
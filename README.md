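# ridge2reef

Linked land–sea modeling of sediment export impacts on coral reefs, for
conservation planners and spatial ecologists working on tropical high
islands. The package couples a watershed soil-loss / sediment-delivery
model to coastal plume dispersal and statistical coral-reef models, so that
land-use change scenarios (logging, agriculture expansion, forest
restoration) and coral bleaching scenarios can be traced through to
predicted changes in reef condition — and the reef impacts traced back to
the specific land areas worth conserving or restoring.

## The model chain

1. **Hillslope erosion (30 m).** Per-cell annual soil loss follows RUSLE,
   `A = R · K · LS · C · P` (t·ha⁻¹·yr⁻¹, scaled by cell area), with
   rainfall erosivity from the Bols relation
   `R = 2.5 P² / (100 (0.073 P + 0.73))` applied to monthly precipitation,
   the Desmet–Govers two-dimensional LS factor, literature C-factors per
   land-cover class, and P ≡ 1.
2. **Delivery to the coast.** A D8-routed, depression-filled DEM yields the
   Borselli hydrologic connectivity index
   `IC = log₁₀(D_up / D_dn)`, `D_up = C̄ S̄ √A`,
   `D_dn = Σ dᵢ / (Cᵢ Sᵢ)`, and the sediment delivery ratio
   `SDR = SDR_max / (1 + exp((IC₀ − IC)/k))` with IC₀ = 0.5, k = 2.0,
   SDR_max = 0.8. Export = soil loss × SDR, summed per watershed at its
   shoreline pour point.
3. **Coastal plumes (60 m).** Each watershed load `s_p` disperses over a
   least-cost surface (composite of depth, distance to mouth, wind
   exposure): `S = s_p · exp(−c²/D_c)`, zeroed beyond 3 km from shore.
   Summing plumes gives a TSS proxy grid.
4. **Marine drivers (60 m).** Depth, distance to shore, bathymetric
   position index (60 / 240 m radii), slope, slope-of-slope, curvatures,
   northness/eastness, circular aspect dispersion, and habitat-patch
   metrics (contiguity, fractal dimension, proximity, Shannon diversity).
5. **Reef models.** Gaussian boosted regression trees per indicator (four
   benthic % covers: CCA, coral, macroalgae, turf — square-root scale; four
   fish biomasses: browsers, grazers, scrapers, predators — fourth-root
   scale), predictors filtered at |r| > 0.7, tuned by ten-fold CV over
   learning rate, tree complexity, bag fraction and tree count. Fish models
   sit below the benthic models in a hierarchy: they are fit on observed
   benthic covers and predict from the predicted (and bleached) benthic
   maps.
6. **Scenarios and impact.** Land-use rules reclassify cover by
   land-use-capability class and logging-concession status; bleaching
   reduces predicted coral cover by 10–30% in depth bands. Per-cell
   significance of scenario differences is classified against the
   domain-wide difference distribution at α = 0.10, and Table-1-style
   summaries (ha, mean change, fish tonnes at 0.36 ha/cell) are produced.
7. **Prioritization.** Watersheds supplying > 90% of the plume load over
   the significantly changed reef cells are linked; within them, the cells
   supplying > 66% of export (or with significant export change) become
   priority land areas, buffered by 100 m and written as polygons.

A fully synthetic ridge-to-reef island (volcanic cone, valley watersheds,
fringing reef / lagoon / barrier crest, reef surveys with known driver
effects) makes the whole chain runnable and testable with no external data.

## Worked example

```r
library(ridge2reef)
cfg <- pipeline_config(
  seed = 1, scenario = "deforestation", bleaching = "high",
  synthetic = list(n_cells = 150, n_sites = 163, noise_sd = 1),
  brt = list(lr_grid = 0.05, tc_grid = 2, bag_grid = 0.75,
             max_trees = 500, folds = 10))
res <- run_pipeline(cfg, "runs/defo_high")

res$sediment$current$result$watershed_loads
#>   watershed_id area_ha load_t_yr
#> 1            1  121.32  61.30983
#> 2            2  126.99  94.03062
#> 3            3  126.45 139.80280
#> 4            4  122.22 108.65423

res$models$benthic$coral
#> <brt_model> coral (sqrt): lr=0.05 tc=2 bag=0.75 trees=55
#>   PDE 59.0%, CV PDE 41.8%
#>   top influence: dist_shore 56.6%, tss 17.4%, slope_of_slope 5.9%, ...

res$assess$summary[, c("indicator", "area_ha", "mean_change", "total_change_t")]
#>    indicator area_ha mean_change total_change_t
#> 1        cca   78.84 -1.42364196             NA
#> 2      coral  100.08 -5.68385781             NA
#> 3 macroalgae   25.20 -0.05075399             NA
#> 4       turf  104.40 -1.36832298             NA
#> 5   browsers   96.84 -0.97737958    -0.09464944
#> 6    grazers  102.60 -3.44555467    -0.35351391
#> 7   scrapers  118.08 -6.29452790    -0.74325785
#> 8  predators   61.20 -4.18619231    -0.25619497

res$prioritize$linked
#> [1] "4" "3"
```

Reading: district export rises from 403.8 to 1,561.6 t·yr⁻¹ under the
deforestation scenario; under deforestation + high bleaching the models
flag ~100 ha of significantly reduced coral cover (−5.7% cover on average)
and a scraper biomass loss of 0.74 t over the flagged area; watersheds 4
and 3 supply > 90% of the plume load over those reefs, and five buffered
priority polygons (≈145 ha) inside them are written to
`runs/defo_high/priority_areas.geojson`.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/ridge2reef run --scenario deforestation --bleaching high \
        --seed 1 --outdir runs/defo_high
Rscript inst/cli/ridge2reef synth --seed 1 --size 200 --outdir runs/island
```

## Documentation

The methods vignette (`vignettes/ridge2reef-methods.Rmd`) documents the
model assumptions, every tunable parameter with its default and rationale,
the synthetic island's construction, numerical choices, and known
limitations.
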
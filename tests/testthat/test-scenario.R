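mk_lu <- function() {
  lu <- matrix(LAND_CLASSES[["native_forest"]], 6, 6)
  lu[1, 1] <- LAND_CLASSES[["pine_plantation"]]
  lu[2, 2] <- LAND_CLASSES[["shrubland"]]
  lu[6, 6] <- NA
  luc <- matrix(6, 6, 6)       # forestry-suitable by default
  luc[3, ] <- 3                # arable row
  luc[4, 4] <- 8               # conservation class
  conc <- matrix(0, 6, 6); conc[, 1:3] <- 1
  list(lu = r2r_grid(lu, 30), luc = r2r_grid(luc, 30),
       conc = r2r_grid(conc, 30))
}

test_that("deforestation converts by LUC class and concession status", {
  f <- mk_lu()
  out <- apply_landuse_scenario(f$lu, f$luc, f$conc,
                                scenario_spec("deforestation", "none"))
  v <- out$land_use$values
  # LUC VI native forest inside concession -> pine
  expect_equal(v[2, 1], LAND_CLASSES[["pine_plantation"]])
  # LUC III (arable) outside concession -> monoculture
  expect_equal(v[3, 5], LAND_CLASSES[["taro_monoculture"]])
  # LUC III inside concession: not forestry-suitable, not converted
  expect_equal(v[3, 2], LAND_CLASSES[["native_forest"]])
  # LUC VIII never converted
  expect_equal(v[4, 4], LAND_CLASSES[["native_forest"]])
  # C grid changes only at reclassified cells
  before_C <- c_factor_grid(f$lu)
  changed <- v != f$lu$values
  same <- !changed & !is.na(v)
  expect_identical(out$C$values[same], before_C$values[same])
  expect_true(all(out$C$values[changed & !is.na(changed)] >
                    before_C$values[changed & !is.na(changed)]))
  # ledger accounts for converted areas
  led <- out$ledger
  expect_equal(sum(led$area_ha_before), sum(led$area_ha_after))
  expect_gt(led$area_ha_after[led$class == "pine_plantation"],
            led$area_ha_before[led$class == "pine_plantation"])
})

test_that("restoration reverts pine to native forest and nothing else", {
  f <- mk_lu()
  out <- apply_landuse_scenario(f$lu, f$luc, f$conc,
                                scenario_spec("restoration", "none"))
  v <- out$land_use$values
  expect_equal(v[1, 1], LAND_CLASSES[["native_forest"]])
  others <- f$lu$values != LAND_CLASSES[["pine_plantation"]]
  expect_identical(v[others], f$lu$values[others])
  # current scenario is the identity
  cur <- apply_landuse_scenario(f$lu, f$luc, f$conc,
                                scenario_spec("current", "none"))
  expect_identical(cur$land_use$values, f$lu$values)
  # unknown class code rejected
  bad <- f$lu; bad$values[5, 5] <- 99
  expect_error(apply_landuse_scenario(bad, f$luc, f$conc,
                                      scenario_spec("current", "none")),
               "unknown")
})

test_that("bleaching applies depth-stratified proportional reductions", {
  depth <- r2r_grid(matrix(c(3, 3, 7, 7, 12, 12, 20, 20, 3, 3, 7, 7,
                             12, 12, 20, 20), 4, 4), 60)
  coral <- r2r_grid(matrix(40, 4, 4), 60)
  low <- apply_bleaching(coral, depth, scenario_spec("current", "low"))
  expect_equal(low$values[1, 1], 36)       # 40 * 0.9 at 3 m
  expect_equal(low$values[3, 1], 40)       # 7 m untouched under low
  mod <- apply_bleaching(coral, depth, scenario_spec("current", "moderate"))
  expect_equal(mod$values[1, 1], 28)       # 40 * 0.7
  high <- apply_bleaching(coral, depth, scenario_spec("current", "high"))
  expect_equal(high$values[1, 1], 28)      # 30% at 0-5 m
  expect_equal(high$values[3, 1], 36)      # 10% at 5-10 m
  expect_equal(high$values[1, 2], 40)      # 12 m unchanged
  expect_equal(high$values[3, 2], 40)      # 20 m unchanged
  # zero cover stays zero; cover never increases
  zero <- grid_like(coral, matrix(0, 4, 4))
  expect_true(all(apply_bleaching(zero, depth,
                                  scenario_spec("current", "high"))$values == 0))
  expect_true(all(high$values <= coral$values))
  expect_error(apply_bleaching(coral, NULL,
                               scenario_spec("current", "low")), "depth")
  # absolute mode subtracts percentage points
  abs_spec <- scenario_spec("current", "low", "absolute")
  expect_equal(apply_bleaching(coral, depth, abs_spec)$values[1, 1], 30)
})
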
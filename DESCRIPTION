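Package: ridge2reef
Title: Linked Land-Sea Modeling of Sediment Export Impacts on Coral Reefs
Version: 0.1.0
Authors@R:
    person("Kubulau", "Modeling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A ridge-to-reef decision-support pipeline that couples watershed
    soil-loss and sediment-delivery models (RUSLE with a Borselli-style
    hydrologic connectivity index) to coastal sediment plume dispersal,
    seafloor-terrain and habitat driver derivation, boosted-regression-tree
    models of coral reef benthic cover and fish biomass, land-use and coral
    bleaching scenario assessment, and spatial prioritization of land areas
    whose conservation or restoration benefits downstream reefs. Includes a
    fully synthetic island generator so the entire pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
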
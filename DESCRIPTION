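Package: nfisim
Title: Simulation and Design-Based Estimation for a National Forest Inventory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate forest landscapes and to run the complete
    sampling and estimation chain of a Nordic-style National Forest
    Inventory (NFI): stratified multi-resolution systematic grids with
    Latin-square panel rotation, nested permanent-plot field protocols
    with angle-count height-tree subsampling, tree-level prediction of
    height, volume, biomass, increment and removals, line-intersect
    sampling of downed deadwood, universal kriging of stratum maps with
    spherical variograms, and design-based expansion estimators with
    conservative (simple-random-sampling) variance estimates. A synthetic
    landscape generator with remeasurement dynamics makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
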
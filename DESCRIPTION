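Package: landcarbon
Title: Land-Use Typology and Aboveground Carbon Accounting from Annual
    Forest-Probability Series
Version: 0.1.0
Authors@R:
    person("Maintainer", "landcarbon", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to map land use and land-use change from annual
    forest-probability raster time series and to account for the
    aboveground carbon consequences. Provides temporal segmentation of
    per-pixel probability trajectories into piecewise-linear segments,
    managed-forest disturbance indices, a nine-class forest-dynamics
    scheme and an eight-type land-use typology (dense forest, forest,
    non-forest, recovery, afforestation, deforestation, rotation and
    large-scale rotation); benchmark-calibrated annual carbon-density
    modelling with per-type stock, gross-flux and net-sink accounting
    against fossil emissions; L-band vegetation optical depth and soil
    moisture observation filtering, orbit combination, logistic
    biomass calibration and per-cell trend tests; cross-product
    comparison utilities; and a synthetic-landscape simulator with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
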
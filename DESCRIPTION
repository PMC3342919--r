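Package: toxsheds
Title: Toxicity-Weighted Watershed Discharge Exposures and County Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking permitted surface-water pollution discharges to
    county mortality rates. Implements cleaning and filtering of permitted
    discharge records, toxicity weighting of chemical releases against a
    packaged 38-chemical ingestion weight table, upstream area-weighted
    accumulation of pollution scores over a tree-structured watershed network,
    population-weighted areal interpolation of watershed scores to counties,
    staged ecological regressions of age-adjusted mortality on discharge
    exposures, Moran's I residual diagnostics, and geographically weighted
    regression with per-county model comparison. A synthetic-data generator
    produces watershed networks, population grids, county partitions, discharge
    records and mortality with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
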
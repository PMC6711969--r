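Package: telemocc
Title: Acoustic Telemetry Residency, Movement and Occurrence Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing passive acoustic telemetry of tagged fish in
    fixed receiver arrays: detection quality control by spatio-temporal
    chronology, rule-based classification of residence and movement events,
    rate-of-movement and minimum transit times from a geodesic
    receiver-distance matrix, construction of daily environmental covariates
    (photoperiod, moon fraction, water temperatures, river discharge), and a
    quasi-Poisson generalized additive model of daily occurrence selected by
    backwards elimination on the generalized cross-validation criterion.
    Includes a synthetic-data generator that emulates an offshore receiver
    grid with seasonal occupancy so the whole pipeline is testable end to
    end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    geosphere,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
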
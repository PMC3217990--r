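Package: marshrise
Title: Tidal Marsh Accretion and Sea-Level Rise Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid tidal-marsh sea-level-rise model: a zero-dimensional,
    tide-resolving sediment accretion simulator (Krone-type mass balance with
    elevation feedback and constant organic accretion) extended to spatially
    explicit, subregion-parameterized projections of intertidal habitat change
    on an elevation raster. Includes synthesis of a repeating tidal month,
    quadratic National Research Council style sea-level-rise trajectories,
    calibration of settling velocity and dry bulk density against published
    sustainability thresholds, elevation-indexed response tables in 10-cm
    increments, tidal datum interpolation (inverse distance weighting),
    habitat classification, area accounting, and a deterministic synthetic
    "toy bay" fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
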
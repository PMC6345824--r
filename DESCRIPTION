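Package: bloomphen
Title: Phytoplankton Bloom Phenology from Float and Satellite Chlorophyll
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates phytoplankton phenology metrics (initiation, peak,
    termination and duration of the main growth period) from surface and
    depth-resolved chlorophyll-a time series using the cumulative-sums-of-
    anomalies change-point method, together with the water-column diagnostics
    used to corroborate the surface signal: euphotic depth from the 1% PAR
    level, first optical depth, surface-layer and depth-integrated
    chlorophyll, mixed-layer depth by a density-threshold criterion, and the
    Brunt-Vaisala buoyancy frequency. Includes fluorometric chlorophyll
    corrections for profiling floats (dark offset, calibration bias,
    non-photochemical quenching), satellite pixel matchup and 5-day
    compositing with gap filling, and a synthetic-data module that emulates
    coupled float/satellite observations of an annual cycle with a subsurface
    chlorophyll maximum, so the whole pipeline is testable without archive
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
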
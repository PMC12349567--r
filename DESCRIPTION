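Package: traymass
Title: Tray-Level Plant Biomass Monitoring from Load-Cell Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibration, disturbance compensation and filtering pipeline for
    continuous, non-destructive plant biomass measurement with tray-mounted
    strain-gauge load cells in hydroponic vertical farms. Converts raw
    multi-cell weight streams into clean tray mass (Hampel outlier rejection,
    linear temperature-drift correction, actuator-disturbance correction via
    correlation analysis, low-pass Butterworth filtering) and into per-plant
    fresh biomass with substrate and plant-count accounting. Includes a
    digital-twin simulator of the sensor physics and growth trials for
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
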
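Package: canopysense
Title: Mobile Urban Green-Infrastructure Monitoring from RGB, Thermal and
    Gas-Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for vehicle-mounted monitoring of urban
    street trees. Computes canopy cover, crown porosity, clumping index and
    leaf area index (LAI, LAIe) from upward-facing RGB frames by blue-channel
    valley thresholding and 5x5 grid gap analysis; derives canopy water-status
    indices (TWSI, Ig, CTD) from radiometric thermal frames using in-frame
    wet/dry reference percentiles; densifies GPS tracks, builds per-tree
    geofences and fuses camera and electronic-nose streams into per-tree
    records; scales the fused table and trains a 10-20-4 feed-forward neural
    network with Levenberg-Marquardt optimisation to predict physiological
    indices from low-cost gas-sensor data; and provides PCA and correlation
    summaries plus seed-deterministic synthetic generators for every input
    modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
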
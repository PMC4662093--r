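Package: geocov
Title: Geographic Covariates for Air Pollution Exposure Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes GIS-derived geographic covariates at point locations
    for land-use-regression style air pollution exposure models: distances
    to roads, transportation depots and physical-geography features;
    circular-buffer summaries of road length (optionally weighted by lane
    counts and road widths), areally weighted census counts, land-use
    proportions and gridded emission totals; and raster extraction of
    vegetation-index (NDVI) summaries and absolute/relative elevation.
    All geometry is planar Euclidean in a single projected coordinate
    system. Includes a seeded synthetic-scene generator with closed-form
    ground truth for end-to-end validation, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
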
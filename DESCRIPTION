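Package: cropsuit
Title: Fuzzy-Set Crop Habitat Suitability Modeling and Climate Projection
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trapezoidal fuzzy-set scoring of environmental criteria
    (temperature, rainfall, solar radiation, soil pH, soil drainage class),
    law-of-the-minimum combination into a 0-100 crop suitability index,
    per-pixel raster evaluation with geographic or projected cell-area
    support, producer-site validation with criterion masking and
    Nash-Sutcliffe / RSR / index-of-agreement statistics, climate-model
    ensemble projection of future suitability with area binning and change
    summaries, and a seeded synthetic-data generator so the whole pipeline
    is testable without external downloads. Ships EcoCrop-derived and
    field-refined breadfruit parameter profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
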
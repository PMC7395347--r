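Package: canopyscan
Title: Thermal and Hyperspectral Panorama Processing for Proximal Canopy
    Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for tower-mounted proximal sensing of forest
    canopies: solar-geometry acquisition scheduling, bit-exact raw sensor
    stream input/output, calibration of hyperspectral line-scan imagery to
    hemispherical-conical reflectance, atmosphere- and emissivity-corrected
    surface temperature retrieval from thermal frame stacks, terrestrial
    laser scanning structural products on angular grids (range, gap
    fraction, canopy and ground masks), sky-stability quality control, and
    vegetation-index time series regressed against daily gross primary
    production. Includes a seed-deterministic scene simulator that
    generates every input with known ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
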
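Package: hyperleaf
Title: Hyperspectral Leaf Chemistry Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for in vivo estimation of leaf chemical traits from
    greenhouse hyperspectral images. Reads ENVI-style band-interleaved-by-line
    (BIL) image cubes, normalizes plant scans by paired blank-chamber reference
    scans to apparent reflectance, segments vegetation with a red-edge NDVI
    threshold, and reduces each plant to a mean reflectance spectrum. Calibrates
    per-trait partial least squares regression (NIPALS PLS1) models with
    leave-one-out cross-validated latent-factor selection and evaluates them
    with RMSE, RPD and mean-normalized MAPE on stratified calibration and
    validation halves. Includes a push-broom imaging simulator that generates
    chemistry-driven synthetic scenes so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr
Config/testthat/edition: 3
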
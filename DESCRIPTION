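Package: canopyphot
Title: UAV Multispectral Estimation and Mapping of Photosynthetic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating the maximum carboxylation rate (Vcmax) and
    maximum electron transport rate (Jmax) of field crops from five-band
    (blue, green, red, red-edge, near-infrared) unmanned-aerial-vehicle
    multispectral imagery. Implements the Farquhar-von Caemmerer-Berry (FvCB)
    model of C3 photosynthesis with Arrhenius temperature scaling and bounded
    nonlinear least-squares fitting of rapid A-Ci gas-exchange curves; excess
    green (ExG) soil and shadow masking with calibration-panel radiometric
    correction and region-of-interest reflectance extraction; a registry of
    broad-band spectral indices (NDVI, NDRE, SCCCI, CVI and others); LASSO
    variable selection with cross-validated penalty; partial least squares
    regression with cross-validated component count and variable importance
    in projection (VIP) scores; and per-pixel trait mapping with per-plot
    summaries. A seeded synthetic-field generator produces nitrogen-gradient
    scenes and forward-simulated A-Ci curves so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
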
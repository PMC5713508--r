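Package: vinepsi
Title: Mapping Vine Stem Water Potential from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the spatial variability of midday stem water
    potential in drip-irrigated vineyards from six-band (530-800 nm) UAV
    multispectral imagery.  The pipeline covers white-panel empirical-line
    reflectance calibration, soil-canopy segmentation by a two-Gaussian fit
    to the NDVI histogram with valley thresholding, thirteen conventional
    spectral indices, single-hidden-layer perceptron regression of stem
    water potential on canopy band reflectances with a restart-based
    hyperparameter grid search and a band-ablation study, validation
    statistics (R2, MAE, RMSE, relative error, modified index of
    agreement), and per-pixel water-stress classification maps.  A seeded
    synthetic vineyard-scene generator provides imagery and ground truth
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    jsonlite
Config/testthat/edition: 3
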
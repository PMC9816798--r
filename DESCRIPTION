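Package: wheatyield
Title: Winter Wheat Yield Estimation from Multispectral and Hyperspectral
    Reflectance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for grid-scale winter wheat yield estimation
    from satellite reflectance. Generates synthetic yield grids, multispectral
    band time series, single-date hyperspectral spectra and planting-management
    tables with the statistical structure the analysis assumes; computes
    vegetation indices (EVI, SR, NDWI, REP) with cloud filtering and monthly
    compositing; screens all two-band hyperspectral index combinations
    (SSI, RSI, NDSI) against yield; trains an LSTM sequence regressor and
    random forest, gradient boosting and support vector baselines; and
    evaluates models with MAE, RMSE, R-squared and permutation feature
    importance, exporting gridded yield maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    zoo,
    randomForest,
    xgboost,
    e1071,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
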
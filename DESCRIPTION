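Package: perchgwr
Title: Geographically Weighted Logistic Regression for Nonstationary
    Species-Environment Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring spatially nonstationary relationships
    between fish presence/absence and environmental covariates, built
    around a geographically weighted logistic regression (GWR) with an
    adaptive Gaussian kernel and AIC-based bandwidth selection. Includes
    survey data cleaning with UTM projection and variance-inflation-factor
    screening, global logistic and penalized-spline additive baselines,
    a stationarity index for local coefficients, model diagnostics (AUC,
    repeated random-split cross-validation, Moran's I permutation tests,
    residual-by-year analysis), k-means zoning of local coefficients with
    gap-statistic selection of the number of clusters, inverse-distance
    interpolation of coefficient surfaces, and a synthetic survey
    generator with known coefficient surfaces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    mgcv,
    stats,
    utils
Suggests:
    ape,
    car,
    geosphere,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
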
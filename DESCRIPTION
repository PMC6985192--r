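Package: lucmap
Title: Land Use and Cover Mapping from Satellite Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for producing annual land use and land cover
    maps from vegetation-index satellite image time series. Implements
    self-organizing-map (SOM) quality control of labelled training samples,
    radial-basis-function support vector machine classification of per-pixel
    annual time series into class probabilities, Bayesian neighborhood
    smoothing of probability rasters, and rule-based post-processing that
    fuses reference deforestation layers into a base map and enforces
    temporal consistency of multi-year class trajectories, including the
    detection of secondary vegetation. Ships a synthetic-data generator that
    emulates class-specific seasonal vegetation-index patterns and small
    patchy raster scenes so the whole pipeline is testable offline, plus
    accuracy-assessment utilities (confusion matrices, user's and producer's
    accuracy, class area series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    quadprog,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
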
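Package: stabdim
Title: Dimensionality of Ecosystem Stability from Vegetation Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three components of ecosystem stability (temporal
    invariability, resistance and resilience) of vegetation productivity from
    gridded monthly vegetation-index and climate time series, and summarises
    their coupling as the dimensionality of stability: the normalized volume of
    the ellipsoid whose semi-axes are square-rooted eigenvalues of the
    correlation matrix among the three components. Includes preprocessing
    (Savitzky-Golay smoothing, low-NDVI pixel filtering, linear detrending,
    z-score anomalies, FAO-56 solar radiation from sunshine hours), a per-pixel
    autoregressive climate-sensitivity model, grazing-intensity derivation from
    livestock records in standard sheep units, space-for-time grouping into
    county-by-grassland-type spatial datasets, between-period attribution via
    bivariate regression and random-forest permutation importance, and a
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
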
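Package: endowater
Title: Surface-Water Trends and Drivers in Endorheic Watersheds from
    Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Endowater", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct annual lake and wetland inundated area in
    closed (endorheic) watersheds from multi-band surface-reflectance imagery
    and to attribute surface-water trends to climate and human water use.
    Implements endmember extraction from spectral-index percentile masks,
    fully constrained least-squares spectral mixture analysis on seasonal
    composites, polygon-based area accounting with functional filtering,
    irrigated-extent mapping from annual maximum NDVI, two-period change
    statistics (Wilcoxon rank-sum, ordinary least-squares trends, change
    vectors), and random-forest permutation variable importance with
    subsampled confidence intervals. A synthetic-watershed generator
    emulates 35-year scene series for snowmelt and monsoonal hydrologic
    regimes so every stage of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
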
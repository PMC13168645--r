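Package: peatwatch
Title: Long-Term Peatland Monitoring with Landsat-Style Composites, RSEI and
    Robust Trend Statistics
Version: 1.0.0
Authors@R:
    person("Peatwatch", "Developers", email = "peatwatch@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for multi-decadal monitoring of raised-bog
    landscapes from annual multispectral composites. Implements QA-bit decoding
    and Collection-2-style product scaling, seasonal scene selection and medoid
    compositing, spectral indicators (NDVI, NDMI, NBR, MNDWI, Tasseled Cap
    Wetness, NDBSI, land surface temperature), two-stage stable-pixel training
    with Random Forest land-cover classification, accuracy assessment, temporal
    majority filtering, class-area accounting and Markov transition matrices, a
    per-year PCA-based Remote Sensing Ecological Index (RSEI) with five-level
    categorisation, Theil-Sen and Mann-Kendall trend statistics with
    trend-free prewhitening, hydroclimate aggregation and anomaly correlation,
    and delta-RSEI change mapping with patch statistics. A synthetic
    raised-bog landscape and climate generator with known ground truth makes
    every stage testable end-to-end without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
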
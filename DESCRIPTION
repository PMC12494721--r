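Package: aminescreen
Title: Plate-Based Screening Analysis of Gut Bacterial Amine Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput screens of xenobiotic
    effects on amine production by gut bacteria. Converts raw 595 nm plate
    absorbance to growth fold changes with aggregation-artifact filtering,
    corrects targeted-metabolomics concentration tables for within-batch
    LC-MS signal drift (boxplot outlier fences, radius-neighbour local
    trend, ratio correction rescaled to the screen median), calls
    plate-matched z-score hits with Benjamini-Hochberg correction and
    dual-replicate criteria, classifies growth concordance, and summarises
    therapeutic-class enrichments, cross-species response correlations,
    dose-response stimulation fractions and quality-control metrics. A
    synthetic multi-batch screen generator with known ground truth supports
    calibration and recovery testing without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
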
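Package: qpcrcam
Title: Threshold-Cycle Analysis for Camera-Based Real-Time PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of real-time PCR monitored with a low-cost
    camera instead of a dedicated fluorescence sensor. Extracts per-cycle
    relative fluorescence from cycle-indexed chip images by grayscale
    region-of-interest averaging, normalizes amplification curves against the
    pre-amplification baseline, log-transforms them and calls fractional
    threshold cycles (Ct). The log threshold is calibrated against a reference
    instrument by grid-search minimization of the distance between Ct vectors,
    per experiment, per instrument set, or globally. Inter-set intensity gain
    differences are equalized by the ratio of endpoint (late-cycle) mean
    intensities before re-optimization, and Ct discrepancies are converted to
    relative initial-concentration error bounds. A seeded synthetic-data
    generator produces amplification curves and rendered image stacks with
    known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports:
    methods,
    stats,
    tools,
    utils,
    graphics,
    S4Vectors,
    withr,
    jsonlite,
    png,
    tiff,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
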
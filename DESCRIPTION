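Package: mirnorm
Title: Reference Gene Identification and Stability Analysis for miRNA RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for identifying and validating stable
    reference genes in two-group RT-qPCR microRNA studies: replicate
    aggregation with quality control, inter-plate calibration,
    amplification-efficiency fitting from dilution series,
    efficiency-corrected relative quantification with log-scale error
    propagation, global-mean candidate selection, geNorm (pairwise-variation
    M values, stepwise exclusion, V series) and NormFinder (model-based
    two-group variance decomposition) stability ranking, equivalence
    testing against a fold-change bound, and assessment of how normalizer
    choice changes target-gene differential-expression calls. Includes a
    synthetic-data generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
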
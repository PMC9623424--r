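Package: l3bodycomp
Title: Opportunistic CT Body Composition at L3 and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies body composition on single-slice axial CT images at
    the third lumbar vertebra (L3) by compartment-constrained Hounsfield-unit
    threshold segmentation into three adipose depots (subcutaneous,
    intermuscular, visceral) and five skeletal-muscle density classes,
    together with waist circumference from the body contour. Provides paired
    pre/post reliability statistics for longitudinal cohorts: percent change
    on group means, Wilcoxon signed-rank tests, and the single-measure
    consistency intraclass correlation ICC(3,1) with F-based confidence
    intervals, including stratification by inter-scan interval. Ships a
    synthetic L3 phantom generator with exact ground-truth compartments and a
    paired-cohort simulator with known variance components, so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
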
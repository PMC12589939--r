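Package: fusionattr
Title: Dual-Analyte Gene Fusion Attribution and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Attributes oncogenic driver gene fusions to the assay that
    detected them (RNA sequencing, DNA sequencing, or both) in cohorts
    profiled with concurrent RNA- and DNA-based next-generation sequencing.
    Implements limit-of-blank based RNA call thresholds, conditional
    cross-analyte DNA positivity rules, fusion partner reconciliation with
    protein-domain constraints, FDA-actionability stratification, cohort
    prevalence and detection-gain statistics, assay concordance metrics
    (positive/negative percent agreement with Wilson score intervals), and a
    calibrated synthetic-cohort generator for validating the full pipeline
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
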
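Package: mdmscreen
Title: Urinary Microbial-Metabolite Exceedance Screening for ASD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for urinary microbially-derived metabolite
    (MDM) screening in two-group (ASD vs typically developing) cohorts.
    Creatinine-normalizes wide-format metabolite tables with explicit
    limit-of-detection handling, builds per-metabolite typically-developing
    (TD) min-max reference ranges, counts strict reference-range exceedances
    into a per-participant MDM Total Score, and classifies participants by an
    at-least-k-exceedances rule with full confusion-matrix reporting.
    Also provides the per-metabolite univariate report (Welch's t-test on raw
    and square-root-transformed values, Benjamini-Hochberg q-values,
    Mann-Whitney AUROC, percent difference, percent above the TD range,
    percent below LOD, metabolite correlation matrix), a ridge-regularised
    Fisher discriminant subset search with leave-one-out cross-validated
    AUROC, and a calibrated synthetic-cohort generator with ground truth for
    testing every stage without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
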
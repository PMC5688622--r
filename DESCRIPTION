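Package: pdprs
Title: Polygenic Risk Score Pipeline for Parkinson Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs a weighted Parkinson disease polygenic risk score
    (PRS) from a published GWAS risk-locus table (log2 odds-ratio weights,
    call-rate panel selection), applies imputation-aware genotype quality
    control (hard-call and INFO filtering, Hardy-Weinberg exact test,
    call-rate filters, principal-component ancestry restriction), and runs
    the downstream association suite: logistic case-control models, ROC
    increment, censored Cox age-at-onset models, Kaplan-Meier tertile
    analysis, and cross-platform-harmonized cerebrospinal-fluid biomarker
    models. Includes a seeded two-cohort synthetic data generator emulating
    the statistical structure of case-control PD studies so the whole
    pipeline is testable without access-controlled genotype data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
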
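Package: nutrimr
Title: One-Sample Summary-Level Mendelian Randomization of Dietary
    Micronutrient Intake and Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for one-sample summary-level Mendelian randomization (MR)
    of dietary micronutrient intake on incident chronic kidney disease (CKD):
    allele-aware harmonization of GWAS summary statistics, the instrument
    selection cascade (suggestive p-value filter, LD clumping, outcome
    association screen, mapped-phenotype pleiotropy screen), six causal-effect
    estimators (fixed-effect IVW, radial IVW, MR-Egger, simple, weighted and
    penalized weighted median), pleiotropy diagnostics (Egger intercept,
    MR-PRESSO global and outlier tests, funnel data), CKD-EPI eGFR phenotyping
    of longitudinal creatinine, polygenic-score validation of instruments, and
    a seeded cohort simulator for estimator calibration. Ships the per-SNP
    instrument sets for dietary phosphorus and vitamins B2, B6 and C from a
    published Korean population-cohort GWAS as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
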
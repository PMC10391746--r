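Package: hematotox
Title: CAR-HEMATOTOX Risk Stratification for BCMA CAR-T Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the CAR-HEMATOTOX (HT) score and the downstream
    toxicity analyses used to risk-stratify patients receiving BCMA-directed
    CAR T-cell therapy for relapsed/refractory multiple myeloma: score
    computation from pre-lymphodepletion labs, longitudinal neutropenia and
    cytopenia endpoints with neutrophil-recovery phenotyping, early-infection
    summaries with cumulative incidence, Kaplan-Meier/log-rank and Cox or
    logistic modelling of survival and toxicity endpoints, non-relapse
    mortality as a competing-risks endpoint, and a calibrated synthetic
    cohort generator so the whole pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
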
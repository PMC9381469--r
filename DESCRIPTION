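Package: SpineCalib
Title: Level-Wise Calibration and Diagnostic Threshold Transfer for
    Opportunistic Spine QCT
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for opportunistic quantitative CT densitometry of the
    spine. Implements exclusion-rule quality control of per-vertebra
    trabecular volumetric bone mineral density (vBMD) measurements
    (Genant fracture grades, degeneration grades), per-patient lumbar
    L1-L3 reference averaging, level-wise Pearson correlation and linear
    calibration of every cervicothoracic vertebra (C2-T12) against the
    lumbar reference, and transfer of lumbar diagnostic cut-offs
    (osteoporosis < 80 mg/ml, osteopenia < 120 mg/ml) to level-specific
    thresholds by evaluating the fitted calibration lines. Ships
    scanner-specific HU-to-vBMD conversion and contrast-phase correction
    machinery, a synthetic cohort generator with a latent lumbar density
    model for ground-truth-known testing, diagnostic classification
    policies, and a file-based pipeline with CSV/JSON/YAML contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
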
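Package: oncoscreen
Title: Subtype-Aware Biomarker Screening and Subgroup Discovery for
    Two-Arm Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A staged biomarker-discovery engine for two-arm randomised
    oncology trials with binary somatic-alteration profiles and tumour
    subtype labels.  Characterises the molecular landscape (hypergeometric
    subtype enrichment, network-free mutual-exclusivity modules), screens
    single alterations and module unions for treatment-arm-specific
    prognosis with Cox proportional-hazards and logistic models, tests
    cross-arm treatment-by-biomarker interactions, selects candidate
    subgroups by their conditional average treatment effect, and reports
    honest subgroup effects via permutation-based multiplicity adjustment
    and bootstrap bias correction with quantile confidence intervals.
    Includes a seeded synthetic-trial generator with mutually exclusive
    alterations, subtype enrichment and planted prognostic and predictive
    effects, plus a repeated cross-validation stability analysis and
    machine-readable TSV/JSON outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    vctrs,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
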
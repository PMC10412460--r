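Package: prbreast
Title: Absolute-Risk Breast Cancer Prognostication with Progesterone-Receptor Incorporation
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ER-stratified, competing-risk absolute-mortality engine for
    early invasive breast cancer in the style of the PREDICT Breast tool,
    together with the machinery needed to fold an externally estimated
    biomarker hazard ratio (progesterone-receptor status) into an existing
    model without refitting it: hazard ratios are rescaled to a
    population-average of unity using the biomarker's prevalence and attached
    to the prognostic index, leaving the baseline hazards and all other
    coefficients untouched.  Includes study-stratified, left-truncated Cox
    estimation of the biomarker effect with the prognostic index as a
    fixed-coefficient offset; an external-validation suite (expected versus
    observed deaths, chi-square goodness of fit, AUC with DeLong comparison,
    quintile calibration, threshold reclassification); seeded synthetic
    cohort generators emulating a multi-study estimation consortium and a
    population-registry validation cohort; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
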
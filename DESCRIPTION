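Package: pescreen
Title: First-Trimester Combined Screening for Preeclampsia and
    Small-for-Gestational-Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for first-trimester multi-marker screening of
    preeclampsia (PE) and small-for-gestational-age (SGA) pregnancies.
    Implements prior risk from maternal characteristics via factor
    likelihood ratios, multiple-of-median (MoM) normalisation of mean
    arterial pressure (MAP), serum PLGF and PAPP-A with gestational-age
    median models and covariate adjustment, posterior risk through
    multivariate-Gaussian marker likelihood ratios, and screening
    performance evaluation (ROC/AUC with DeLong comparison, optimal
    cutoffs, detection rates at fixed false-positive rates, exact
    binomial confidence intervals). Includes a calibrated synthetic
    cohort generator so the full pipeline can be exercised and tested
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    pROC
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
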
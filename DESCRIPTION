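Package: fhprs
Title: Family History and Polygenic Risk in COPD Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing self-reported family history with a
    polygenic risk score (PRS) as predictors of moderate-to-severe COPD and
    related outcomes in smoker case-control cohorts. Implements spirometry-based
    case/control/exclusion derivation, family-history harmonisation, per-cohort
    PRS standardisation and tertile dichotomisation, the three nested regression
    models (family history only, PRS only, both), Firth penalised logistic
    regression for imbalanced cohorts, discrimination and calibration metrics
    (AUROC with DeLong confidence intervals and paired tests, scaled Brier
    scores, adjusted R-squared, MSE), attributable fractions, multiplicative and
    additive (RERI) interaction, natural direct/indirect effect mediation with
    bootstrap inference, biserial exposure-mediator correlation, and
    inverse-variance fixed-effect meta-analysis with heterogeneity statistics.
    A synthetic-cohort generator with the same statistical structure supports
    testing and power exploration without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
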
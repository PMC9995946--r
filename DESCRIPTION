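Package: sfascreen
Title: Structure-Function Association Models for Cognitive Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Cohort-specific ridge regressions that predict cognitive test
    scores (MMSE, ADAS-13, RAVLT immediate recall, Trail Making Test part B,
    Digit Symbol Substitution Test) from FreeSurfer-derived regional brain
    morphometry, and a screening classifier that assigns a subject to the
    cognitively normal, MCI, or dementia cohort whose structure-function
    association model best reproduces their observed scores, fused across
    tests by majority voting.  Includes readers for FreeSurfer stats files
    and delimited subject tables, a calibrated three-cohort synthetic data
    generator with known planted associations, age-trend and slope-interaction
    analytics, and impurity-based feature-importance rankings aggregated over
    tree ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
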
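Package: bctscore
Title: Blood Cell Count Score Discovery for Two-Arm Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of threshold-based blood-cell-count
    ratio scores (BCTscore) in two-arm oncology trials. Screens longitudinal
    complete-blood-count ratio biomarkers (NLR, PLR, LMR, NMR) with Cox
    proportional-hazards scans over decile cutoff fractions, filters out
    control-arm-prognostic biomarkers, narrows absolute integer cutoffs,
    enumerates and selects threshold-combination risk scores by
    time-dependent AUC, and assesses predictive versus prognostic value via
    within-stratum treatment hazard ratios and treatment-by-score
    interaction tests. Includes a synthetic two-arm trial generator with
    longitudinal log-normal cell counts and planted prognostic or predictive
    effects, plus a from-scratch survival-statistics core (Cox partial
    likelihood with Efron ties, Kaplan-Meier, stratified log-rank,
    IPCW time-dependent ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
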
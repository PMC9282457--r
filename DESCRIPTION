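Package: dbmarker
Title: Continuous Digital Biomarkers from Sparse Daily Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns sparse, missing-not-at-random daily questionnaire data from
    addiction-monitoring eHealth systems into continuous digital biomarkers
    (wellbeing index WeBe-i and motivation/self-confidence index MotSC-i) by
    per-day averaging, gap-decay imputation and exponential smoothing. Includes
    the question-grouping step (correlation-matrix PCA with varimax rotation),
    exacerbation-event detection from breathalyzer records, LSTM-based relapse
    forecasting over patient-level splits, MCC/AUC evaluation at the
    MCC-maximizing threshold, and a synthetic-cohort generator so the full
    pipeline runs without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
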
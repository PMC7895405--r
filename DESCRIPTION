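Package: cllscore
Title: CD200-Augmented Matutes Scoring for Flow-Cytometry Diagnosis of CLL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for immunophenotypic scoring of
    B-cell chronic lymphoproliferative disorders. Generates synthetic listmode
    flow-cytometry cohorts with matched isotype controls, performs CD45/SSC
    lymphocyte gating and CD19+ B-cell selection, quantifies marker expression
    (percent-positive against an isotype threshold, mean fluorescence
    intensity ratio, log-decade intensity pattern), computes the classical
    five-marker Matutes score, its CD200-augmented extension and a simplified
    four-marker score, and evaluates diagnostic accuracy (exact binomial
    confidence intervals, tie-corrected rank AUC with DeLong intervals,
    Youden-optimal ROC cutoffs, McNemar and Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
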
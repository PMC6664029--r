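Package: revsig
Title: Disease Signature Reversal Scoring and Drug Combination Synergy
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A transcriptome-driven drug-repositioning toolkit for
    castration-resistant prostate cancer and similar settings. Builds a
    disease expression signature by moderated-t / fixed-effect
    meta-analysis across microarray studies, scores drug-induced landmark
    gene profiles against the signature with the Connectivity-Map style
    reverse gene expression score (RGES) and its per-compound summary
    (sRGES), integrates IC50/AUC compound activity to stratify active and
    inactive compounds, screens for reversal genes with
    leave-one-compound-out cross-validation, and predicts drug-combination
    sensitivity and synergy from a drug-target matrix with a
    target-inhibition maximization/minimization averaging model. Ships a
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
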
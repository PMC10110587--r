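Package: polyverify
Title: Second-Opinion Screening of Polygraph Examiner Conclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quality-assurance tool for classical polygraph screenings.
    Parses multi-channel physiological recordings with question timestamps
    from a documented NCCA-ASCII-style text dialect, extracts a
    600-dimensional stimulus-locked feature row per (test, topic), scores
    each screening topic with a two-level stacking ensemble trained under
    leak-free stratified group K-fold validation, and ranks examiner
    "No Deception Indicated" conclusions that the model strongly
    contradicts so they can be queued for human review. A synthetic-cohort
    simulator with known deception ground truth and a configurable
    examiner-error rate makes every stage testable without access to a
    proprietary screening archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    data.table,
    xgboost,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
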
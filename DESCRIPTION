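Package: lcmspanel
Title: Label-Free LC/MS Biomarker Discovery and Serum Panel Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for indirect blood-based
    biomarker discovery. Aligns label-free LC/MS peptide-ion maps across samples
    (two-step retention-time normalization anchored on internal standards,
    m/z-RT-charge feature matching, least-squares intensity normalization),
    flags differentially expressed peptides, aggregates them into prioritized
    candidate proteins (fold-change, multiplicity and subcellular-localization
    filters), integrates candidates across tissue, cell-line and
    conditioned-medium discovery platforms, and builds multi-marker serum
    panels by elastic-net logistic regression with the regularization weight
    chosen by bootstrap out-of-bag AUC maximization. Ships a synthetic-data
    module that generates every input with known ground truth: in-silico
    tryptic digests, paired tumor/control ion maps with retention-time drift
    and log-normal intensity noise, and case/control serum cohorts calibrated
    to published marker medians and interquartile ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
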
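Package: mirprospect
Title: Prospective Blood miRNA Biomarker Analysis for Matched
    Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for prospective blood microRNA biomarker
    discovery in matched case-control cohort studies, motivated by COPD
    cohorts followed for later cancer development. Implements probe-level
    preprocessing (background subtraction, replicate collapsing, quantile
    normalization), dual parametric and rank-based genome-wide
    differential expression with Benjamini-Hochberg adjustment and
    per-miRNA ROC-AUC, cutoff-free running-sum category enrichment with
    an exact dynamic-programming p-value alongside hypergeometric set
    tests, clinical confounder screens, class-weighted gradient-boosted
    tree signature selection with repeated stratified cross-validation,
    and a noncentral-t power solver for unbalanced two-sample designs.
    A synthetic cohort generator with planted effects makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    limma,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
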
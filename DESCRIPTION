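Package: sigcore
Title: Signed Gene-Signature Scoring, Core-Gene Extraction and Survival
    Evaluation for Prognostic Expression Signatures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for interrogating signed multi-gene prognostic
    expression signatures in breast cancer cohorts. Implements the
    Score for Signature Match (SSM) sample classifier, expression-based
    HER2 amplicon status calling with IHC concordance statistics,
    Kaplan-Meier / Cox / weighted log-rank survival comparison of
    signature-match groups, ROC analysis of outcome aggressiveness,
    exhaustive sub-signature enumeration with pairwise co-occurrence
    core-gene extraction, correlation-based substitute-gene discovery,
    composition-matched random-signature null models with empirical
    false detection rates, and a synthetic cohort generator with
    pathway-blocked expression, proportional-hazards survival and a
    planted HER2 amplicon subpopulation. Ships the 17-gene HTICS
    signature for HER2-positive, ER-negative disease and its published
    core subsets as built-in fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
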
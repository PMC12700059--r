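Package: placebotalk
Title: Predicting Placebo Response in Chronic Pain from Interview Language
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to label placebo responders from twice-daily pain-rating
    diaries by one-sided permutation tests, turn topic-tagged interview
    transcripts into pooled document embeddings, predict responder status
    with a nested-cross-validated L1-regularized linear support-vector
    classifier, and interpret the fitted decision boundary by projecting
    words, sentences, and density-based sentence clusters into the model's
    semantic space. Includes a seeded synthetic-cohort generator (diaries,
    transcripts, ground truth) with the statistical structure the analysis
    assumes, so the full pipeline is testable without access to clinical
    interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
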
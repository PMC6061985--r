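Package: gdrex
Title: Gene-Disease Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level extraction of gene-disease associations from
    biomedical literature by supervised joint ensemble learning. Combines a
    rich handcrafted feature set (word windows, relational keywords, lexical,
    conceptual, context, pattern-template and negation features) with
    skip-gram word embeddings trained by negative sampling, and classifies
    candidate gene-disease pairs with a bagged ensemble of instance-weighted
    RBF-kernel support vector machines aggregated by majority voting.
    Includes readers for four gold-corpus dialects (EU-ADR, GAD, CoMAGC,
    PolySearch styles) normalised to a JSON-lines interchange format, a
    deterministic rule-based linguistic annotator, stratified 10-fold
    cross-validated precision/recall/F-score and ROC evaluation, and a
    synthetic corpus generator for fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    kernlab,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
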
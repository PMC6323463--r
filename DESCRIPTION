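Package: cdsearch
Title: Passage Retrieval for Clinical Decision Support from Laboratory
    Test Reports
Version: 0.1.0
Authors@R:
    person("Open", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A clinical decision support (CDS) search engine that retrieves
    short textbook passages relevant to free-text laboratory test reports.
    Implements ontology-driven concept detection and translation, synonym
    expansion with down-weighting, multilevel (passage-level and
    document-level) pseudo-relevance feedback with damped IDF-style term
    weighting, multi-model retrieval (TF-IDF, BM25, Dirichlet language
    model) with min-max score fusion, and negation-differential re-ranking
    that boosts passages describing abnormal findings when the query itself
    reports an abnormal result. Ships TREC-style evaluation metrics (P@N,
    R-precision, nDCG, MRR, paired comparison) and a seeded synthetic
    collection generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
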
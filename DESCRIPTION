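Package: necrotext
Title: Text Mining of Free-Text Wildlife Necropsy Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A describe-explore-examine pipeline for mining free-text wildlife
    necropsy records exported from semi-structured pathology registers. Builds
    a corpus with document-level metadata from a column-mapped CSV export,
    summarises and filters signalment variables, explores themes through
    word co-occurrence (phi) networks and latent Dirichlet allocation fitted
    by a collapsed Gibbs sampler, and quantifies clinicopathologic findings
    with TF-IDF keyword retrieval and keyword-in-context negation detection
    using a punctuation-bounded phrase rule. Includes a seeded synthetic
    record generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
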
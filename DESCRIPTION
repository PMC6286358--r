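Package: speechgraph
Title: Non-Semantic Word-Graph Analysis of Speech Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds directed word multigraphs from speech transcripts and
    quantifies their structure with four attributes: lexical diversity
    (node count, N), short-range recurrence (repeated edges, RE),
    long-range recurrence (largest strongly connected component, LSC) and
    graph size (average shortest path, ASP). Attributes are computed on
    moving 30-word windows with 50 percent overlap, normalized against
    word-shuffled null graphs, and modelled across years of age or
    education with a bounded, SEM-weighted saturating-exponential fit.
    Includes the statistical battery used in developmental and clinical
    speech-graph studies (rank and partial rank correlations, multiple
    regression, Kruskal-Wallis and Wilcoxon group tests with Bonferroni
    correction, distributional checks, proportion tests, permutation
    nulls) and a synthetic-cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
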
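Package: essTransfer
Title: Cross-Species Transfer of Gene Essentiality Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how training-set selection affects machine-learning
    prediction of essential genes across microbial species. Provides a
    phylogeny-driven synthetic multi-species benchmark generator
    (class-conditional features whose discriminative direction drifts by
    Brownian motion along a divergence-time tree, per-species label noise,
    and growth-condition/lifestyle-dependent relabeling), extraction of
    fifteen widely used gene features (expression, phyletic age, protein
    domains, PPI network centralities, protein length, codon adaptation
    index, and homology counts), a naive Bayes essentiality classifier for
    mixed continuous/categorical features with missing values, reciprocal
    transfer-accuracy matrices (AUC, PPV at k, TPR at prevalence) with
    dispersion and divergence-time correlation analyses, and experiment
    suites for incomplete, integrated, and rule-selected training sets with
    a random-integration permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
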
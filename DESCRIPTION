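Package: hceloss
Title: Hierarchical Cross-Entropy Loss for Ontology-Aware Cell-Type
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates cell-type classifiers whose label space is
    a directed acyclic graph (DAG) of cell-ontology terms linked by is_a
    relations. Implements the hierarchical cross-entropy (HCE) loss, which
    propagates predicted probability mass from descendant cell types to
    their ancestors through a reachability matrix before taking the
    negative log-likelihood, alongside the standard weighted cross-entropy.
    Provides ontology ingestion (OBO subset or edge-list), pruning to an
    observed label set, node taxonomy (leaf/internal, connected/isolated),
    descendant-aware macro F1 evaluation, linear and multilayer-perceptron
    classifiers with a seeded training loop, per-class paired comparisons
    with Holm-Bonferroni correction, and a synthetic single-cell atlas
    generator with mixed-granularity annotations and study-level
    distribution shift for out-of-distribution benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
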
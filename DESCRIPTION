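Package: ontopop
Title: Semi-Supervised Ontology Population with Word Embeddings
Version: 0.1.0
Authors@R:
    person("Ontopop", "Maintainers", email = "maintainers@ontopop.org",
           role = c("aut", "cre"))
Description: Populates a fixed ontology skeleton (a multi-parent directed
    acyclic graph of classes, seeded with a few known instances per class)
    with candidate instances by embedding similarity.  Provides a bespoke
    TSV ontology format with structural analytics (depth, paths to root,
    instances per class), a deterministic text-preprocessing pipeline, a
    skip-gram word-embedding trainer plus loaders for word2vec/GloVe text
    vectors, a nearest-centroid mapper with an alpha-weighted combination
    of sibling and parent similarity, Jaccard/Hamming/random baselines,
    success metrics (precision, hop distance) and structural metrics
    (granularity, cohesiveness), repeated seeded-skeleton experiments, and
    a synthetic generator of clustered ontologies and embeddings for fully
    offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
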
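Package: phenossl
Title: Self-Supervised Attributed-Network Embeddings for Gene-Phenotype
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts gene-phenotype associations from a gene attributed
    network that combines protein-protein interactions with Gene Ontology
    annotation indicators.  Node attributes are smoothed with a generalized
    Laplacian filter, a linear encoder is pretrained with a self-supervised
    pretext task (cosine-similarity-ranked positive and negative gene pairs,
    binary cross-entropy reconstruction), and the resulting embeddings feed
    a multi-label deep classifier over phenotype ontology terms.  Includes
    ontology ingestion with true-path-rule propagation, CAFA-style macro and
    micro AUPR and Fmax evaluation with term-size groups, 5-fold and
    temporal validation splits, and a seeded synthetic benchmark generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
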
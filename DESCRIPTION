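Package: teratorank
Title: Semi-Supervised Ranking of Compounds for Placental Crossing and
    Teratogenicity with Knowledge-Graph Clique Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds drug-drug similarity matrices from transcriptomic
    perturbation signatures (consensus characteristic-direction vectors,
    cosine similarity) and from chemical structure (circular fingerprints
    with inverse-document-frequency bit weighting), scores unlabeled
    compounds by mean similarity to labeled positives (semi-supervised
    label propagation), evaluates rankings with a Kolmogorov-Smirnov-like
    bridge-plot enrichment score normalized by label permutations, and
    assembles a typed birth-defect/gene/drug knowledge graph supporting
    co-expression edge construction, over-representation likelihood-ratio
    statistics, and three-node clique extraction. Includes seeded
    synthetic-data generators with planted structure so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
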
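Package: interologr
Title: Cross-Species Protein-Protein Interaction Prediction by
    Multi-Strategy Interolog Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions (PPIs) in a target
    organism from experimentally known PPIs of one or more source
    organisms by generalized interolog mapping, and scores each candidate
    with a multi-strategy score S = Ssim + Srank + Scon combining
    normalized joint sequence similarity, a normalized within-template
    rank, and a phylogenetic conservation score across source organisms.
    Includes readers for BLAST tabular homology searches, PPI edge lists
    and evolutionary-distance configurations; relative specificity
    similarity (RSS) over the Gene Ontology for functional validation and
    negative-set construction; benchmark evaluation (ROC, precision,
    F-beta threshold selection, ortholog enrichment); reconstruction and
    topological analysis of the predicted network (power-law degree
    exponent, module connectivity, one-layer module extension); and a
    synthetic-data generator so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
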
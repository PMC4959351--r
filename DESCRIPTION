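Package: ontorelate
Title: Relatedness Networks over Multi-Ontology Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds hybrid biomedical knowledge networks that link concepts
    from several ontologies (diseases, symptoms, gene product properties,
    chemicals) through typed, weighted, directed edges, and computes
    relatedness networks around an anchor concept with a recursive
    set-theoretic inference engine. Includes pruning operators (the
    inter-relationship-only "interesting set", per-relation-type link
    masks with confidence and significance thresholds, hub exclusion),
    corpus-derived TF-IDF edge weights, readers for OBO ontologies and
    edge tables, evaluation harnesses for differential-diagnosis recall
    and disease-pair discovery, and synthetic network generators for
    testing the inference machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
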
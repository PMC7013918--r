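Package: glionet
Title: Differential Protein-Protein Interaction Network Analysis for
    Disease Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for differential protein-protein
    interaction (PPI) network analysis of disease subtypes, developed around
    glioma (general glioma, glioblastoma multiforme, low-grade astrocytoma)
    but generic over any set of conditions. Expression tables are reduced to
    seed gene sets by an expression cutoff and a Gene Ontology keyword
    filter; first-order PPI networks are built around the seeds from
    interaction tables in a BioGRID-like or STRING-links-like dialect, with
    confidence-score and taxonomy filtering; networks are compared through
    graph set algebra (merged intersections, unions and per-disease unique
    difference networks) and topology statistics; overlapping protein
    complexes are detected by greedy cohesiveness maximisation
    (ClusterOne-style); GO over-representation is tested with the
    hypergeometric distribution and Benjamini-Hochberg correction; and
    cross-database hub and isolated-node consensus reports are produced.
    A synthetic-data generator plants complexes, hubs, isolated seeds and an
    enriched GO term so that every stage has a recovery test that runs
    without any network access.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
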
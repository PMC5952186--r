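Package: netpharm
Title: Network Pharmacology Analysis of Herb Targets on Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for network-pharmacology target prioritization on
    protein-protein interaction (PPI) networks. Partitions a PPI network into
    topological modules by modularity-based community detection, scores every
    (module, seed gene group) pair with a one-sided Fisher exact test and fold
    enrichment, summarizes shortest-path proximity of drug targets to gene
    groups (min/max/average distance with reachability accounting), and calls
    key candidate targets as proteins lying at average distance below a
    threshold from a key disease module and from the aggregate co-morbid
    disease and symptom gene groups. Includes readers for edge-list/SIF
    networks, phenotype-gene and herb-ingredient-target tables and GMT gene-set
    collections, a seeded planted-partition synthetic-data generator for
    benchmarking, and report writers producing reproducible TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
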
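Package: pangenet
Title: Network Graphs for Bacterial Pangenome Analysis
Version: 0.1.0
Authors@R: person("Pangenet", "Developers", email = "pangenet@example.org",
    role = c("aut", "cre"))
Description: Builds, transforms and analyses the three network views of a
    bacterial pangenome: genome-genome similarity graphs weighted by the
    Jaccard similarity coefficient over accessory gene content, gene-gene
    co-occurrence graphs computed from the inverted presence/absence matrix,
    and gene synteny graphs whose edges count the genomes in which two gene
    families are adjacent. Provides readers for Roary, Rtab and PIRATE-style
    presence/absence tables and edge lists, graph reduction operators
    (edge-weight thresholds, k-nearest-neighbour sparsification, frequency
    filters, component pruning, contraction of highly conserved syntenic
    edges), Markov (MCL) and Louvain clustering, Fisher-exact enrichment of
    cluster membership against genome metadata, gene-cluster distribution
    profiles, a seed-deterministic synthetic pangenome simulator, and
    exporters to Graphia '.layout', GraphML and tabular formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    yaml,
    xml2
Config/testthat/edition: 3
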
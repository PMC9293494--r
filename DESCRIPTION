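Package: herbnetpharm
Title: Network Pharmacology Screening of Herbal Compound-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained network-pharmacology pipeline for
    herb-compound-target studies: ADME activity filtering of compounds by
    oral bioavailability and drug-likeness, construction of compound-target
    bipartite networks and protein-protein interaction subnetworks from
    user-supplied edge lists, key-target screening by six topological
    centrality measures (degree, closeness, betweenness, eigenvector,
    local average connectivity and edge-clustering-based network
    centrality), MCODE-style dense-module detection with the density-times-
    size cluster score, hypergeometric over-representation analysis of
    gene sets in GMT collections, and the 2^-ddCt qPCR fold-change
    statistic. Seeded synthetic-data generators emulate every pipeline
    input with planted ground truth (active compounds, network hubs, a
    dense module, an enriched term), so the whole workflow is testable
    offline without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
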
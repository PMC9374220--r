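Package: bridesnet
Title: Population Graphs and BRIDES Path-Type Analysis for Conservation
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds population graphs from multilocus codominant genotypes
    using conditional genetic distance with covariance-based edge pruning,
    computes node-based connectivity and node-removal statistics, classifies
    subgraph node pairs into the six BRIDES path types (breakthrough,
    roadblock, impasse, detour, equal, shortcut) relative to a complete
    graph, and runs a weighted stepwise node-selection algorithm with tie
    branching to prioritize populations under proactive or reactive
    conservation scenarios. Includes a synthetic genotype generator
    (Dirichlet drift under island or two-cluster migration structure) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
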
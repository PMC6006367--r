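Package: antrail
Title: Distributed Maintenance and Repair of Ant Trail Networks on
    Pheromone-Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation and analysis of how arboreal turtle
    ants (Cephalotes goniodontus) maintain a trail network and route
    around broken links.  Provides pheromone-weighted undirected graphs,
    the Weighted, RankEdge and Unweighted per-step edge-choice models, a
    synchronous multi-ant engine with deposit-and-decay dynamics, node
    queueing, explore traverse-and-return and dead-end pheromone
    suppression, benchmark lattice networks and road-network sampling,
    convergence and pruning metrics (success rate, path entropy, path
    length, path elimination, path length pruning, robustness), and
    maximum-likelihood fitting of the exploration and decay parameters to
    timestamped junction-choice observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
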
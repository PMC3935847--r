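Package: ctrlcascade
Title: Controllability of Directed Networks Under Cascading Edge Failures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying how the structural
    controllability of a directed network (the minimum number of driver
    nodes, computed from a maximum matching) evolves during
    betweenness-load cascading failures. Provides directed Erdos-Renyi and
    static-model scale-free generators, raw-count shortest-path edge
    loads, a load-capacity cascade model with a tolerance parameter,
    random and intentional (highest-load) edge-attack strategies,
    critical/ordinary/redundant edge classification, an
    exact-controllability cross-check based on eigenvalue multiplicity,
    and realization-averaged experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
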
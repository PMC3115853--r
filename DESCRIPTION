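Package: netcentral
Title: Shortest Path Based Centrality Metrics for Large Sparse Networks
Version: 1.0.0
Authors@R:
    person("netcentral", "developers", email = "netcentral@example.org",
           role = c("aut", "cre"))
Description: Computes the four classical shortest-path centrality metrics
    (betweenness, closeness, eccentricity, stress) on undirected, unweighted
    networks such as protein-protein interaction or gene co-expression graphs.
    The computational core is a frontier-synchronous, edge-parallel formulation
    of all-pairs shortest paths over a two-array edge representation, paired
    with Brandes-style dependency accumulation, provided both as a compiled
    whole-array kernel and as a literal per-edge reference loop with a tested
    equivalence contract. Includes a seeded Barabasi-Albert scale-free network
    generator, edge-list text input/output, a brute-force geodesic-enumeration
    oracle for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
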
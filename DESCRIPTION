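Package: intramol
Title: Enumerate and Index Bonded n-Body Intramolecular Interactions via
    Iterated Line Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exhaustive enumeration, indexing and classification of bonded
    n-body intramolecular interactions (bonds, bends, proper and improper
    dihedrals, degenerate 3-cycles) from a molecular connectivity graph,
    by iterating the line graph transformation. Provides the standard
    matrix representations (adjacency, incidence, degree, Kirchhoff,
    signless Laplacian), closed-form interaction counts with consistency
    checksums and a brute-force subgraph oracle, the multipartite
    interaction-hierarchy DAG with atomic index-sequence backtracking and
    4-body type classification, a left-right planarity test and the line
    index (first nonplanar iterated line graph), fixture-graph generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
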
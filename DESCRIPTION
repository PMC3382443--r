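Package: mcenum
Title: Maximum Clique Enumeration for Correlation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact enumeration of all maximum cliques in finite simple graphs,
    aimed at dense graphs built by thresholding gene co-expression
    correlations.  Implements the classic Bron-Kerbosch maximal clique
    backtracking as a benchmark, a fixed-parameter-style Maximum Clique
    Finder with greedy lower bounds and coloring/degree preprocessing, two
    maximum-clique-only enumeration strategies (intelligent backtracking and
    parameterized branching), and the maximum clique cover and essential
    vertex set reductions that shrink a graph while preserving every maximum
    clique.  Includes a correlation-graph builder for expression matrices, a
    synthetic graph test kit (Moon-Moser, planted overlapping cliques,
    expected-degree random graphs), an exhaustive brute-force oracle for
    small graphs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
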
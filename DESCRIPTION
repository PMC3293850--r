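Package: netquant
Title: Topological Network Descriptors for Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a catalogue of topological network descriptors for
    undirected simple connected graphs: distance-based indices (Wiener,
    Harary, Balaban J, compactness, product of row sums, hyper-distance-path,
    Skorobogatov-Dobrynin statistics), adjacency- and degree-based indices
    (total adjacency, Zagreb group indices, Randic, complexity index B,
    normalized edge complexity), partition-based Shannon entropies
    (topological information content over automorphism orbits,
    Bonchev-Trinajstic indices, Bertz complexity, radial centric, vertex
    degree equality, Balaban-like U and X, graph vertex complexity), and
    parametric graph entropies built from information functionals over
    j-spheres with configurable weighting schemes and scaling constant.
    Includes graph I/O (edge list, GraphML), fixture trees, random-graph
    generators, batch descriptor-matrix computation over graph collections,
    and a synthetic tree-population generator for branching studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
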
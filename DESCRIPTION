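Package: rlpnet
Title: Reverse Link Prediction for Epidemic Mitigation on Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the existing edges of a contact or transport network with
    neighborhood-similarity link-prediction scores (common neighbors, Jaccard,
    preferential attachment, resource allocation, Adamic-Adar), greedily removes
    top-ranked edges while keeping the network connected, and evaluates the
    epidemic-mitigation effect of the removals through the largest adjacency
    eigenvalue and a walk-count criterion, with edge betweenness centrality as
    the comparison baseline. Includes readers for plain edge lists and
    MatrixMarket files, seeded synthetic graph generators (scale-free,
    small-world, regular lattice, uniform random), and a comparison workflow
    that selects the best-performing score function at a common removal budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
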
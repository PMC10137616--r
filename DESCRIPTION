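Package: CentralityCosDist
Title: Seed-Based Node Prioritization in Biological Networks via
    Centrality Vectors and Cosine Similarity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks the nodes of an undirected biological network (protein-
    protein interaction or co-expression) by their similarity to a set of
    seed genes. Each node is encoded as a vector of graph centrality
    measures (degree, betweenness, closeness, eigenvector, PageRank,
    personalized PageRank, current-flow/information centrality, clustering
    coefficient) and nodes are ranked by their mean cosine similarity to
    the seed nodes in that feature space. Also provides two classical
    comparator rankers (random walk with restart and iterative
    hypergeometric module expansion), an analysis of which centralities
    drive unsupervised node cluster structure (DBSCAN / k-means labels,
    random-forest permutation importance, ternary coordinates), a planted
    seed-module benchmark generator, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    randomForest,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
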
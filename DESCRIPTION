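Package: dendroblend
Title: Multi-View Similarity Blending for Low-Cost Hierarchical Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchical clustering of a similarity matrix under Dasgupta's
    cost objective. Derives structurally diverse dendrogram views of the
    input (recursive spectral bisection, recursive k-means, centroid
    linkage), converts each view back into a similarity matrix, and learns
    a constrained non-linear blend of all matrices with a surrogate-assisted
    optimizer before a final average-linkage pass. Includes a beam-search
    baseline over average linkage, synthetic benchmark generators (among
    them an adversarial decoy-clique instance), and evaluation metrics:
    Dasgupta-cost improvement, normalized Robinson-Foulds distance,
    adjusted Rand index at a cut, Mann-Whitney community ranking,
    ontology-expanded F1 and Jaccard bootstrap stability.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    lhs,
    randomForest,
    jsonlite,
    withr,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
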
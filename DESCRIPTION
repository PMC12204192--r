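Package: seqspace
Title: Hierarchical Clustering and Exploration of Protein Sequence Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring large protein sequence spaces through
    hierarchical clustering. Builds sequence similarity networks from
    all-vs-all homology searches (BLAST/MMSeqs tabular output), detects
    sequence neighborhoods as connected components at multiple bitscore
    cut-offs with a streaming, chunked union-find that never loads the full
    edge list, and clusters protein language-model embeddings with a
    hierarchy-consistent bisecting K-means or weighted-linkage cosine
    agglomeration. Includes chance-adjusted cluster-agreement metrics
    (ARI/AMI), a physics-style nested circle-packing layout for visualizing
    cluster hierarchies, profile- and centroid-based representative
    selection, and even sampling of sequence space for phylogenetics.
    Seeded synthetic-data generators make the whole pipeline testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
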
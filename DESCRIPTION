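Package: tfnetdev
Title: Transcription Factor Network Inference from Developmental Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering functional transcription-factor (TF)
    networks from short developmental RNA-seq time courses. Covers FPKM
    normalisation and expressed-gene filtering, a negative-binomial exact
    test for adjacent-timepoint differential expression with
    Benjamini-Hochberg FDR control and a periodic/continuous gene
    partition, weighted co-expression module detection (soft-thresholded
    adjacency, topological overlap, dynamic tree cut, eigengene merging,
    fuzzy c-means trend decomposition), five co-expression metrics for TF
    pairs feeding a supervised random-forest interaction classifier,
    cohesive overlapping network partitioning with a size-matched
    random-network significance null, two-tailed hypergeometric
    pathway-overlap testing, and mutual-information (data-processing
    inequality pruned) plus tree-ensemble directed gene-regulatory-network
    inference with hub ranking. Ships a seeded synthetic time-course
    generator with planted modules, TF functional groups and
    regulator-target effects so that every stage can be benchmarked
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    igraph,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
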
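Package: scens
Title: Ensemble Similarity Network Clustering and Denoising for Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single-cell RNA-seq expression profiles by building an
    ensemble cell-cell similarity network from repeated random subsamples of
    high-mean, high-variance feature genes, suppressing dropout (zero-inflation)
    noise with a random walk with restart over the network, estimating the
    number of clusters with the Rubin index, and deriving final labels by
    iterative correlation-based merging of K-means seed clusters. Ships a
    zero-inflated negative-binomial simulator with planted cluster structure,
    pair-counting clustering metrics (Jaccard, adjusted Rand, normalized mutual
    information), and gene-set agreement metrics so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: SingleCell, Clustering, Network, GeneExpression, RNASeq
RoxygenNote: 7.3.3
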
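Package: epivec
Title: Paragraph-Vector Sequence Embeddings for Enhancer-Promoter
    Interaction Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns fixed-length embedding vectors for variable-length
    enhancer and promoter DNA sequences by treating each sequence as a
    sentence of overlapping k-mer words and fitting a distributed-memory
    paragraph-vector model with hierarchical softmax over a binary Huffman
    tree. Pairs of sequence embeddings are concatenated and classified as
    interacting or non-interacting with gradient boosted regression trees
    under stratified cross-validation. An attention weighting ranks the
    k-mers of each sequence by their contribution to its embedding, for
    downstream motif analysis. A synthetic-data generator with planted
    position-weight-matrix motifs provides ground-truth corpora for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Epigenetics, GenePrediction, MachineLearning, Classification,
    FunctionalGenomics, Sequencing
RoxygenNote: 7.3.3
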
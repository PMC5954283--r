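## Generics, accessors and show methods for the core classes.

#' Accessors for vocabulary, model and report objects
#'
#' Accessor generics used across the package: \code{vocabSize} returns
#' the number of observed tokens V (the reserved UNK token is not
#' counted), \code{tokens} and \code{tokenCounts} the token strings and
#' their corpus frequencies, \code{vocabulary} the
#' [KmerVocabulary-class] of a corpus or model, \code{wordVectors} /
#' \code{docVectors} the embedding matrices (columns are vectors),
#' \code{docVector} one trained sequence embedding by document id,
#' \code{codeLengths} the per-token Huffman code lengths,
#' \code{cvMetrics} / \code{cvPredictions} the per-fold metric table and
#' held-out predictions of a [CVReport-class], and \code{pairTable} /
#' \code{externalFeatures} the components of a [PairDataset-class].
#'
#' @param x the object.
#' @param docId character document id (for \code{docVector}).
#' @return The component named by the accessor.
#' @examples
#' vocab <- buildVocabulary(list(c("ATG", "TGC", "ATG")), k = 3)
#' vocabSize(vocab)
#' tokenCounts(vocab)
#' @name epivec-accessors
#' @aliases vocabSize tokens tokenCounts vocabulary wordVectors
#'   docVectors docVector codeLengths cvMetrics cvPredictions pairTable
#'   externalFeatures
NULL

#' @rdname epivec-accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))
#' @rdname epivec-accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname epivec-accessors
#' @export
setGeneric("tokenCounts", function(x) standardGeneric("tokenCounts"))
#' @rdname epivec-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname epivec-accessors
#' @export
setGeneric("wordVectors", function(x) standardGeneric("wordVectors"))
#' @rdname epivec-accessors
#' @export
setGeneric("docVectors", function(x) standardGeneric("docVectors"))
#' @rdname epivec-accessors
#' @export
setGeneric("docVector", function(x, docId) standardGeneric("docVector"))
#' @rdname epivec-accessors
#' @export
setGeneric("codeLengths", function(x) standardGeneric("codeLengths"))
#' @rdname epivec-accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))
#' @rdname epivec-accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))
#' @rdname epivec-accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname epivec-accessors
#' @export
setGeneric("externalFeatures", function(x) standardGeneric("externalFeatures"))

#' @rdname epivec-accessors
#' @export
setMethod("vocabSize", "KmerVocabulary", function(x) length(x@tokens))
#' @rdname epivec-accessors
#' @export
setMethod("tokens", "KmerVocabulary", function(x) x@tokens)
#' @rdname epivec-accessors
#' @export
setMethod("tokenCounts", "KmerVocabulary",
    function(x) setNames(x@counts, x@tokens))
#' @rdname epivec-accessors
#' @export
setMethod("vocabulary", "KmerCorpus", function(x) x@vocabulary)
#' @rdname epivec-accessors
#' @export
setMethod("vocabulary", "EmbeddingModel", function(x) x@vocabulary)
#' @rdname epivec-accessors
#' @export
setMethod("vocabSize", "KmerCorpus", function(x) vocabSize(x@vocabulary))
#' @rdname epivec-accessors
#' @export
setMethod("vocabSize", "EmbeddingModel", function(x) vocabSize(x@vocabulary))
#' @rdname epivec-accessors
#' @export
setMethod("wordVectors", "EmbeddingModel", function(x) x@wordVectors)
#' @rdname epivec-accessors
#' @export
setMethod("docVectors", "EmbeddingModel", function(x) x@docVectors)

#' @rdname epivec-accessors
#' @export
setMethod("docVector", "EmbeddingModel", function(x, docId) {
    stopifnot(is.character(docId), length(docId) == 1L)
    if (!docId %in% colnames(x@docVectors))
        stop("document '", docId, "' was not part of training; ",
             "use inferVector() for unseen sequences", call. = FALSE)
    x@docVectors[, docId]
})

#' @rdname epivec-accessors
#' @export
setMethod("codeLengths", "HuffmanTree", function(x) lengths(x@codes))
#' @rdname epivec-accessors
#' @export
setMethod("cvMetrics", "CVReport", function(x) x@metrics)
#' @rdname epivec-accessors
#' @export
setMethod("cvPredictions", "CVReport", function(x) x@predictions)
#' @rdname epivec-accessors
#' @export
setMethod("pairTable", "PairDataset", function(x) x@pairs)
#' @rdname epivec-accessors
#' @export
setMethod("externalFeatures", "PairDataset", function(x) {
    if (nrow(x@external) == 0L) NULL else x@external
})

setMethod("show", "KmerVocabulary", function(object) {
    cat("KmerVocabulary of", length(object@tokens), object@k, "-mers",
        sprintf("(capacity 4^%d = %d)", object@k, 4L^object@k), "\n")
    cat("  total token count:", sum(object@counts),
        "| UNK windows:", object@unkCount, "\n")
})

setMethod("show", "KmerSentence", function(object) {
    cat("KmerSentence", object@docId, ":", length(object@tokens),
        sprintf("%d-mers (stride %d)", object@k, object@s), "\n")
    if (length(object@kmers))
        cat("  ", paste(head(object@kmers, 6L), collapse = " "),
            if (length(object@kmers) > 6L) "..." else "", "\n")
})

setMethod("show", "KmerCorpus", function(object) {
    cat("KmerCorpus:", length(object@sentences), "documents,",
        sum(lengths(object@sentences)), "tokens,",
        "V =", vocabSize(object@vocabulary),
        sprintf("(k = %d, s = %d)", object@k, object@s), "\n")
    tab <- table(object@roles)
    cat("  roles:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "HuffmanTree", function(object) {
    cl <- codeLengths(object)
    cat("HuffmanTree:", length(object@codes), "leaves,",
        object@nNodes, "internal nodes\n")
    cat(sprintf("  code lengths %d..%d, expected length %.3f bits\n",
        min(cl), max(cl),
        sum(cl * object@counts) / sum(object@counts)))
})

setMethod("show", "TrainConfig", function(object) {
    cat(sprintf(
        "TrainConfig: k=%d s=%d m=%d d=%d | %s softmax, %s composition | %d epochs, alpha %.3g -> %.3g, seed %d\n",
        object@k, object@s, object@m, object@d, object@mode,
        object@composition, object@epochs, object@alpha, object@alphaMin,
        object@seed))
})

setMethod("show", "EmbeddingModel", function(object) {
    cat("EmbeddingModel (", object@config@mode, " softmax)\n", sep = "")
    cat("  ", ncol(object@docVectors), "document vectors, ",
        vocabSize(object@vocabulary), " word vectors, d = ",
        object@config@d, "\n", sep = "")
    show(object@config)
})

setMethod("show", "PairDataset", function(object) {
    n <- nrow(object@pairs)
    cat("PairDataset:", n, "pairs (",
        sum(object@pairs$label == 1L), "positive /",
        sum(object@pairs$label == 0L), "negative )\n")
    if (nrow(object@external))
        cat("  external features:", ncol(object@external), "columns\n")
})

setMethod("show", "PairFeatures", function(object) {
    cat("PairFeatures:", nrow(object@features), "pairs x",
        ncol(object@features), "features\n")
})

setMethod("show", "GBRTConfig", function(object) {
    cat(sprintf("GBRTConfig: alpha = %.3g, nTrees = %d, depth = %d\n",
        object@alpha, object@nTrees, object@depth))
})

setMethod("show", "CVReport", function(object) {
    m <- object@metrics
    cat("CVReport over", object@nFolds, "stratified folds\n")
    for (nm in c("f1", "auroc", "auprc"))
        cat(sprintf("  %-6s %.4f (sd %.4f)\n", nm,
            mean(m[[nm]]), sd(m[[nm]])))
})

setMethod("show", "AttentionProfile", function(object) {
    i <- which.max(object@weights)
    cat("AttentionProfile", object@docId, ":", length(object@weights),
        "tokens\n")
    cat(sprintf("  top k-mer %s (pos %d, weight %.4g)\n",
        object@kmers[i], object@positions[i], object@weights[i]))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nEnhancers, "enhancers x",
        object@nPromoters, "promoters,",
        object@nCandidatePairs, "candidate pairs\n")
    cat("  enhancer classes:",
        paste(names(object@enhancerMotifs), collapse = ", "),
        "| promoter classes:",
        paste(names(object@promoterMotifs), collapse = ", "), "\n")
    cat(sprintf("  distances %g-%g bp, %d bins, %d negative(s) per positive\n",
        object@minDistance, object@maxDistance, object@nBins,
        object@negativesPerPositive))
})
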
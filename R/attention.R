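## attention: rank the k-mers of a sequence by their contribution to
## its embedding, and export top-weighted k-mers for motif analysis.

#' Attention weights of a sequence's k-mers
#'
#' Scores every token t of sequence i by the softmax-normalized dot
#' product between the sequence's document vector x_i and the token's
#' word vector w_{c_{i,t}}:
#' \deqn{\alpha_{it} = \frac{\exp(x_i^T w^{c_{i,t}})}{\sum_j \exp(x_i^T w^{c_{i,j}})}}
#' The denominator runs over the tokens of sentence i only, so the
#' weights of one sequence sum to 1.  Duplicated k-mers each keep their
#' own (identical) weight; deduplication happens only at export.
#'
#' @param model a trained [EmbeddingModel-class].
#' @param x the sequence: a document id known to the model, or a
#'   [KmerSentence-class].
#' @param docVec optional d-vector to use as x_i (e.g. from
#'   [inferVector()]) when the document was not part of training.
#' @return An [AttentionProfile-class].
#' @export
attentionWeights <- function(model, x, docVec = NULL) {
    stopifnot(is(model, "EmbeddingModel"))
    cfg <- model@config
    if (!is(x, "KmerSentence"))
        stop("pass the sequence as a KmerSentence (see tokenize()); ",
             "for whole-corpus profiles use attentionProfiles()",
             call. = FALSE)
    docId <- x@docId
    kmers <- x@kmers
    positions <- seq.int(1L, by = cfg@s, length.out = length(kmers))
    if (is.null(docVec)) {
        if (!docId %in% colnames(model@docVectors))
            stop("document '", docId, "' unseen by the model; pass ",
                 "docVec = inferVector(model, sentence)", call. = FALSE)
        docVec <- model@docVectors[, docId]
    }
    if (length(kmers) == 0L)
        stop("empty sentence (T = 0): no tokens to weight", call. = FALSE)
    idx <- encodeTokens(model, kmers)
    V <- vocabSize(model@vocabulary)
    cols <- ifelse(idx == 0L, V + 1L, idx)
    z <- as.vector(crossprod(model@wordVectors[, cols, drop = FALSE], docVec))
    w <- softmaxVec(z)
    ## exp() can underflow to exactly 0 for tokens far from the document
    ## vector; clamp so weights stay in (0, 1)
    w <- pmax(w, .Machine$double.xmin)
    w <- w / sum(w)
    new("AttentionProfile", docId = docId, kmers = kmers,
        positions = as.integer(positions), weights = w)
}

#' Attention profiles for a whole corpus
#'
#' Computes [attentionWeights()] for every document of a corpus against
#' the model trained on it.
#'
#' @param model a trained [EmbeddingModel-class].
#' @param corpus the [KmerCorpus-class] the model was trained on.
#' @return A named list of [AttentionProfile-class] objects.
#' @export
attentionProfiles <- function(model, corpus) {
    stopifnot(is(corpus, "KmerCorpus"))
    toks <- model@vocabulary@tokens
    out <- lapply(seq_along(corpus@docIds), function(i) {
        enc <- corpus@sentences[[i]]
        kmers <- ifelse(enc == 0L, "UNK", toks[pmax(enc, 1L)])
        sent <- new("KmerSentence", docId = corpus@docIds[i],
                    tokens = enc, kmers = kmers,
                    k = corpus@k, s = corpus@s)
        attentionWeights(model, sent)
    })
    names(out) <- corpus@docIds
    out
}

#' Top-weighted k-mers across sequences
#'
#' For each selected sequence, returns its \code{n} highest-attention
#' k-mers (ties broken by first occurrence along the sequence),
#' deduplicated within the sequence.  With \code{positivesOnly} the
#' selection is restricted to sequences participating in at least one
#' positive pair, matching the use of attention to nominate candidate
#' motifs from interacting elements.
#'
#' @param profiles a list of [AttentionProfile-class] objects.
#' @param n integer, k-mers to keep per sequence (>= 1; default 1).
#' @param positivesOnly logical; restrict to positive-pair members.
#' @param dataset a [PairDataset-class]; required when
#'   \code{positivesOnly = TRUE}.
#' @return A data.frame with columns \code{kmer}, \code{doc_id},
#'   \code{weight}, \code{rank}.
#' @export
topKmers <- function(profiles, n = 1L, positivesOnly = FALSE,
                     dataset = NULL) {
    if (n < 1L)
        stop("n must be >= 1", call. = FALSE)
    if (positivesOnly) {
        if (is.null(dataset))
            stop("positivesOnly = TRUE requires a PairDataset", call. = FALSE)
        pos <- pairTable(dataset)[pairTable(dataset)$label == 1L, ]
        keep <- unique(c(pos$enh_id, pos$prom_id))
        profiles <- Filter(function(p) p@docId %in% keep, profiles)
    }
    rows <- lapply(profiles, function(p) {
        ## stable sort: descending weight, ties by first occurrence
        o <- order(-p@weights, seq_along(p@weights))
        km <- p@kmers[o]
        keep <- !duplicated(km)
        km <- km[keep]
        wt <- p@weights[o][keep]
        take <- seq_len(min(n, length(km)))
        data.frame(kmer = km[take], doc_id = p@docId,
                   weight = wt[take], rank = take,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Export selected k-mers as FASTA
#'
#' Writes one FASTA record per selected k-mer with header
#' \code{<doc_id>|rank<r>|w=<weight>} (weights at 6 significant
#' digits), suitable as input to external motif-enrichment tools.
#'
#' @param selection a data.frame from [topKmers()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportKmersFasta <- function(selection, path) {
    if (is.null(selection) || nrow(selection) == 0L)
        stop("empty selection: nothing to export", call. = FALSE)
    headers <- sprintf("%s|rank%d|w=%s", selection$doc_id, selection$rank,
                       signif(selection$weight, 6))
    seqs <- Biostrings::DNAStringSet(selection$kmer)
    names(seqs) <- headers
    Biostrings::writeXStringSet(seqs, filepath = path)
    invisible(path)
}

#' Export full attention profiles as TSV
#'
#' @param profiles a list of [AttentionProfile-class] objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportProfilesTsv <- function(profiles, path) {
    rows <- lapply(profiles, function(p)
        data.frame(doc_id = p@docId, position = p@positions,
                   kmer = p@kmers, weight = p@weights,
                   stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
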
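## Binary Huffman coding over the k-mer vocabulary: the output
## structure of the hierarchical softmax.  Frequent tokens get short
## codes, so frequent prediction targets are reached by short root
## paths during training.

#' Build the binary Huffman tree of a vocabulary
#'
#' Constructs the optimal prefix code over the vocabulary's token
#' frequencies by repeatedly merging the two lowest-count subtrees.
#' The merge queue is ordered by (count, then lexicographically
#' smallest contained token) so the tree is fully reproducible.  For
#' each leaf the 0/1 code and the ordered internal nodes on its root
#' path are recorded; a vocabulary of V tokens yields V - 1 internal
#' nodes, and more frequent tokens never receive longer codes than
#' less frequent ones.
#'
#' @param vocab a [KmerVocabulary-class] with at least two tokens, or a
#'   named integer vector of counts.
#' @return A [HuffmanTree-class].
#' @examples
#' buildHuffman(c(A = 4L, B = 1L, C = 1L))
#' @export
buildHuffman <- function(vocab) {
    if (is(vocab, "KmerVocabulary")) {
        counts <- vocab@counts
        toks <- vocab@tokens
    } else {
        counts <- as.integer(vocab)
        toks <- names(vocab) %||% as.character(seq_along(vocab))
    }
    V <- length(counts)
    if (V < 2L)
        stop("Huffman tree needs a vocabulary of at least 2 tokens ",
             "(got ", V, "); the hierarchical softmax is degenerate",
             call. = FALSE)

    ## Node arrays: 1..V leaves, V+1..2V-1 internal nodes in creation
    ## order.  minTok carries the lexicographically smallest token in
    ## each subtree for deterministic tie-breaking.
    nNode <- 2L * V - 1L
    cnt <- c(as.numeric(counts), rep(NA_real_, V - 1L))
    minTok <- c(toks, rep(NA_character_, V - 1L))
    parent <- integer(nNode)
    bit <- integer(nNode)            # code bit assigned at the parent
    alive <- c(rep(TRUE, V), rep(FALSE, V - 1L))

    for (i in seq_len(V - 1L)) {
        idx <- which(alive)
        o <- order(cnt[idx], minTok[idx], method = "radix")
        a <- idx[o[1L]]; b <- idx[o[2L]]
        newNode <- V + i
        cnt[newNode] <- cnt[a] + cnt[b]
        minTok[newNode] <- min(minTok[a], minTok[b])
        parent[c(a, b)] <- newNode
        bit[a] <- 0L; bit[b] <- 1L   # smaller (count, token) branch = 0
        alive[c(a, b)] <- FALSE
        alive[newNode] <- TRUE
    }

    codes <- vector("list", V)
    paths <- vector("list", V)
    for (leaf in seq_len(V)) {
        cd <- integer(0); pt <- integer(0)
        node <- leaf
        while (parent[node] != 0L) {
            cd <- c(bit[node], cd)
            pt <- c(parent[node] - V, pt)   # internal node index 1..V-1
            node <- parent[node]
        }
        codes[[leaf]] <- cd
        paths[[leaf]] <- pt
    }
    names(codes) <- toks
    names(paths) <- toks
    new("HuffmanTree", codes = codes, paths = paths,
        nNodes = V - 1L, counts = as.integer(counts))
}
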
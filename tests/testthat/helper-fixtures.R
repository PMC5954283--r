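## Shared fixtures and independent oracles for the test suite.
## Everything is generated in code; no stored data files.

BASES <- c("A", "C", "G", "T")

randomDNA <- function(n, prob = rep(0.25, 4)) {
    paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

## Named set of random sequences with role-style ids.
randomSeqSet <- function(n, len, role = "ENHANCER", seed = 1) {
    withr::with_seed(seed, {
        out <- vapply(seq_len(n), function(i) randomDNA(len), character(1))
        names(out) <- paste0(role, "_", seq_len(n))
        out
    })
}

## A small trained model + corpus for probability / attention tests.
tinyModel <- function(n = 10, len = 80, k = 3, d = 8, m = 3, epochs = 3,
                      mode = "hierarchical", composition = "mean",
                      seed = 42) {
    seqs <- randomSeqSet(n, len, seed = seed)
    corp <- kmerCorpus(seqs, k = k, s = 1)
    model <- trainEmbedding(corp, trainConfig(
        k = k, d = d, m = m, epochs = epochs, mode = mode,
        composition = composition, seed = seed))
    list(corpus = corp, model = model)
}

## ---- independent oracles -------------------------------------------------

## Brute-force sliding-window token count: enumerate starts 0, s, 2s, ...
oracleTokenCount <- function(L, k, s) {
    if (L < k) return(0L)
    length(seq.int(0L, L - k, by = s))
}

## Independent Huffman construction (repeated which.min merging on a
## plain table; tie-break on count only).  Returns total weighted code
## length, the quantity that is invariant across valid Huffman trees.
oracleHuffmanCost <- function(counts) {
    stopifnot(length(counts) >= 2)
    q <- as.numeric(counts)      # queue of subtree weights
    cost <- 0
    while (length(q) > 1) {
        o <- order(q)[1:2]
        merged <- q[o[1]] + q[o[2]]
        cost <- cost + merged    # every merge adds its weight once per level
        q <- c(q[-o], merged)
    }
    cost
}

## Brute-force hierarchical-softmax leaf probability: walk the stored
## code/path and multiply sigmoids, computed directly from model slots.
oracleLeafProbs <- function(model, h) {
    V <- vocabSize(model@vocabulary)
    z <- as.vector(crossprod(model@nodeVectors, h))
    vapply(seq_len(V), function(leaf) {
        code <- model@tree@codes[[leaf]]
        path <- model@tree@paths[[leaf]]
        prod(1 / (1 + exp(-(1 - 2 * code) * z[path])))
    }, numeric(1))
}

## Compose the predictor h for a context, mirroring the model contract.
composeH <- function(model, contextIdx, docId) {
    V <- vocabSize(model@vocabulary)
    cols <- ifelse(contextIdx == 0L, V + 1L, contextIdx)
    Wc <- model@wordVectors[, cols, drop = FALSE]
    x <- model@docVectors[, docId]
    if (model@config@composition == "concat") c(as.vector(Wc), x)
    else (rowSums(Wc) + x) / (model@config@m + 1)
}

## Brute-force auROC: fraction of positive/negative pairs correctly
## ordered, ties counted half.
oracleAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

## Independent average-precision computation via an explicit threshold
## loop over unique scores.
oracleAp <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    prevRec <- 0
    ap <- 0
    for (t in th) {
        sel <- scores >= t
        prec <- sum(labels[sel]) / sum(sel)
        rec <- sum(labels[sel]) / sum(labels)
        ap <- ap + (rec - prevRec) * prec
        prevRec <- rec
    }
    ap
}

## Mean attention weight on motif-overlapping vs background tokens,
## aggregated over a whole corpus, using generator ground truth.
attentionRecovery <- function(model, corpus, truth, k = 6L) {
    profiles <- attentionProfiles(model, corpus)
    mw <- bw <- numeric(0)
    for (id in names(profiles)) {
        p <- profiles[[id]]
        pl <- truth[truth$doc_id == id, , drop = FALSE]
        if (nrow(pl) == 0L) { bw <- c(bw, p@weights); next }
        ov <- rep(FALSE, length(p@positions))
        for (r in seq_len(nrow(pl)))
            ov <- ov | (p@positions <= pl$end[r] &
                        p@positions + k - 1L >= pl$start[r])
        mw <- c(mw, p@weights[ov])
        bw <- c(bw, p@weights[!ov])
    }
    c(motif = mean(mw), background = mean(bw))
}

## Mean within-class and between-class cosine similarity of document
## vectors, for planted-motif recovery checks.
classCosine <- function(model, classes) {
    D <- docVectors(model)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    C <- crossprod(D)
    cls <- unique(classes)
    within <- mean(c(C[classes == cls[1], classes == cls[1]],
                     C[classes == cls[2], classes == cls[2]]))
    between <- mean(C[classes == cls[1], classes == cls[2]])
    c(within = within, between = between)
}

## Write a tiny FASTA file by hand (independent of Biostrings).
writeTestFasta <- function(lines, path = tempfile(fileext = ".fa")) {
    writeLines(lines, path)
    path
}
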
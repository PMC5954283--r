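## embedding: distributed-memory paragraph-vector training with
## hierarchical softmax (Huffman tree) or exact softmax.

#' Training configuration for the paragraph-vector model
#'
#' Defaults are the setting used throughout the package: k = 6, stride
#' s = 1, context window m = 20, embedding dimension d = 100.  The m
#' context word vectors and the document vector combine into the
#' softmax predictor h according to \code{composition}.  The learning
#' rate decays linearly from \code{alpha} to \code{alphaMin} over
#' training.
#'
#' @param k,s,m,d integers: word length, stride, context window,
#'   embedding dimension.
#' @param epochs integer full passes over the corpus (default 5).
#' @param alpha,alphaMin numeric initial and floor learning rate.
#' @param mode \code{"hierarchical"} (default; Huffman-tree softmax) or
#'   \code{"exact"} (dense softmax \eqn{y = b + Uh}, practical only for
#'   small vocabularies).
#' @param composition how context word vectors and the document vector
#'   combine into the predictor h: \code{"mean"} (default) averages
#'   them in one shared d-space, the composition the attention
#'   weighting \eqn{\alpha \propto \exp(x^T w)} presumes;
#'   \code{"concat"} concatenates them into \eqn{R^{(m+1)d}}.
#' @param seed integer seed for initialization and epoch shuffling.
#' @return A [TrainConfig-class].
#' @examples
#' trainConfig(d = 16, m = 5, epochs = 2)
#' @export
trainConfig <- function(k = 6L, s = 1L, m = 20L, d = 100L, epochs = 5L,
                        alpha = 0.03, alphaMin = 1e-4,
                        mode = c("hierarchical", "exact"),
                        composition = c("mean", "concat"), seed = 1L) {
    mode <- match.arg(mode)
    composition <- match.arg(composition)
    new("TrainConfig", k = as.integer(k), s = as.integer(s),
        m = as.integer(m), d = as.integer(d), epochs = as.integer(epochs),
        alpha = alpha, alphaMin = alphaMin, mode = mode,
        composition = composition, seed = as.integer(seed))
}

emptyTree <- function() new("HuffmanTree", codes = list(), paths = list(),
                            nNodes = 0L, counts = integer(0))

#' Train paragraph-vector embeddings on a k-mer corpus
#'
#' Learns one d-dimensional word vector per vocabulary token and one
#' d-dimensional document vector per sequence by stochastic gradient
#' descent on the average log probability of predicting each token from
#' the m preceding tokens and the document vector.  The document vector
#' is shared across the contexts of its own sentence only; word vectors
#' are shared corpus-wide.  Only full m-length contexts are used, so
#' sentences with T <= m tokens are skipped with a warning.  Word and
#' document vectors are initialized uniformly at random from the seed;
#' softmax parameters start at zero.  Training is single-threaded and
#' bit-reproducible for a given seed.
#'
#' @param corpus a [KmerCorpus-class]; its tokenization (k, s) must
#'   match the configuration.
#' @param config a [TrainConfig-class].
#' @param verbose logical; log the resolved configuration and the mean
#'   log-probability before and after training.
#' @return An [EmbeddingModel-class] whose document vectors are the
#'   sequence embedding features.
#' @examples
#' seqs <- setNames(
#'   vapply(1:8, function(i)
#'     paste(sample(c("A","C","G","T"), 60, TRUE), collapse = ""), ""),
#'   paste0("ENHANCER_", 1:8))
#' corp <- kmerCorpus(seqs, k = 3, s = 1)
#' model <- trainEmbedding(corp, trainConfig(k = 3, d = 8, m = 3,
#'                                           epochs = 2))
#' dim(docVectors(model))
#' @export
trainEmbedding <- function(corpus, config = trainConfig(), verbose = FALSE) {
    stopifnot(is(corpus, "KmerCorpus"), is(config, "TrainConfig"))
    if (corpus@k != config@k || corpus@s != config@s)
        stop("corpus tokenization (k=", corpus@k, ", s=", corpus@s,
             ") does not match config (k=", config@k, ", s=", config@s, ")",
             call. = FALSE)
    vocab <- corpus@vocabulary
    V <- vocabSize(vocab)
    if (V < 2L)
        stop("vocabulary must contain at least 2 tokens", call. = FALSE)
    N <- length(corpus@sentences)
    d <- config@d; m <- config@m
    usable <- lengths(corpus@sentences) > m
    if (!any(usable))
        stop("no sentence has more than m = ", m,
             " tokens; lower m or use longer sequences", call. = FALSE)
    if (!all(usable))
        warning(sum(!usable), " sentence(s) with T <= m skipped",
                call. = FALSE)

    hierarchical <- config@mode == "hierarchical"
    if (!hierarchical && V > 1024L)
        warning("exact softmax with V = ", V,
                " is slow; intended for small vocabularies", call. = FALSE)
    tree <- if (hierarchical) buildHuffman(vocab) else emptyTree()
    concat <- config@composition == "concat"
    hdim <- if (concat) (m + 1L) * d else d

    init <- withSeed(config@seed, list(
        W = matrix(runif(d * (V + 1L), -0.5 / d, 0.5 / d), nrow = d),
        D = matrix(runif(d * N, -0.5 / d, 0.5 / d), nrow = d)))
    S <- if (hierarchical) matrix(0, hdim, V - 1L)
         else matrix(0, hdim, V)
    b <- if (hierarchical) numeric(0) else numeric(V)

    if (verbose) {
        message("training paragraph-vector model: N=", N,
                " documents, V=", V, " tokens")
        show(config)
    }
    if (config@epochs == 0L)  # untrained model: random init, zero softmax
        fit <- list(wordVectors = init$W, docVectors = init$D,
                    outputVectors = S, bias = b)
    else fit <- cppTrainPVDM(unname(corpus@sentences), seq_len(N),
                        init$W, init$D, S, b,
                        tree@codes, tree@paths, hierarchical, concat,
                        m, config@epochs, config@alpha, config@alphaMin,
                        config@seed, FALSE)
    docV <- fit$docVectors
    colnames(docV) <- corpus@docIds
    model <- new("EmbeddingModel",
        wordVectors = fit$wordVectors, docVectors = docV,
        nodeVectors = if (hierarchical) fit$outputVectors
                      else matrix(numeric(0), 0L, 0L),
        softmaxU = if (hierarchical) matrix(numeric(0), 0L, 0L)
                   else fit$outputVectors,
        softmaxB = if (hierarchical) numeric(0) else as.numeric(fit$bias),
        tree = tree, vocabulary = vocab, config = config,
        version = "epivec-model-1")
    if (verbose)
        message(sprintf("mean log-probability after training: %.4f",
                        corpusLogProb(model, corpus)))
    model
}

## Encode a sentence's tokens as indices into a model's vocabulary
## (0 = UNK / out-of-vocabulary).
encodeTokens <- function(model, x) {
    if (is(x, "KmerSentence")) x <- x@kmers
    if (is.character(x)) {
        i <- match(x, model@vocabulary@tokens)
        i[is.na(i)] <- 0L
        i
    } else as.integer(x)
}

#' Mean log-probability of a corpus under a model
#'
#' Evaluates the training objective: the mean over sentences of the
#' per-sentence average log probability of each token given its
#' m-token context and the sentence's document vector (set
#' \code{perSentence = FALSE} for a flat mean over all contexts).
#'
#' @param model an [EmbeddingModel-class].
#' @param corpus the [KmerCorpus-class] the model was trained on (its
#'   document ids must all be known to the model).
#' @param perSentence logical; weight every sentence equally
#'   (1/(T_i - m) within each sentence), as in the training objective.
#' @return A single numeric value (always negative).
#' @export
corpusLogProb <- function(model, corpus, perSentence = TRUE) {
    stopifnot(is(model, "EmbeddingModel"), is(corpus, "KmerCorpus"))
    di <- match(corpus@docIds, colnames(model@docVectors))
    if (anyNA(di))
        stop("corpus documents missing from model: ",
             paste(head(corpus@docIds[is.na(di)], 3L), collapse = ", "),
             call. = FALSE)
    hierarchical <- model@config@mode == "hierarchical"
    cppMeanLogProb(unname(corpus@sentences), di,
                   model@wordVectors, model@docVectors,
                   if (hierarchical) model@nodeVectors else model@softmaxU,
                   model@softmaxB,
                   model@tree@codes, model@tree@paths, hierarchical,
                   model@config@composition == "concat",
                   model@config@m, perSentence)
}

#' Next-word probability distribution
#'
#' Probability of every vocabulary token being the next word, given m
#' context tokens and a document.  In exact mode the distribution is
#' the softmax of \eqn{y = b + Uh} with h the concatenation of the m
#' context word vectors and the document vector; in hierarchical mode
#' the probability of each token is the product of branch sigmoids
#' along its root path in the Huffman tree.  Either way the returned
#' values lie in (0, 1) and sum to 1 over the vocabulary.
#'
#' @param model an [EmbeddingModel-class].
#' @param context m context tokens: k-mer strings or vocabulary
#'   indices.
#' @param docId a document id known to the model.
#' @return A named numeric vector of length V summing to 1.
#' @export
nextWordProbability <- function(model, context, docId) {
    stopifnot(is(model, "EmbeddingModel"))
    m <- model@config@m; d <- model@config@d
    if (length(context) != m)
        stop("context must contain exactly m = ", m, " tokens (got ",
             length(context), ")", call. = FALSE)
    if (!docId %in% colnames(model@docVectors))
        stop("unknown document id '", docId, "'", call. = FALSE)
    idx <- encodeTokens(model, context)
    V <- vocabSize(model@vocabulary)
    cols <- ifelse(idx == 0L, V + 1L, idx)
    Wc <- model@wordVectors[, cols, drop = FALSE]
    x <- model@docVectors[, docId]
    h <- if (model@config@composition == "concat") c(as.vector(Wc), x)
         else (rowSums(Wc) + x) / (m + 1)
    if (model@config@mode == "exact") {
        y <- as.vector(crossprod(model@softmaxU, h)) + model@softmaxB
        p <- softmaxVec(y)
    } else {
        z <- as.vector(crossprod(model@nodeVectors, h))
        p <- vapply(seq_len(V), function(leaf) {
            code <- model@tree@codes[[leaf]]
            path <- model@tree@paths[[leaf]]
            prod(sigmoid((1 - 2 * code) * z[path]))
        }, numeric(1))
    }
    setNames(p, model@vocabulary@tokens)
}

#' Infer an embedding vector for a new sequence
#'
#' Optimizes a fresh document vector for a sentence by SGD on the
#' training objective with the word vectors and softmax parameters
#' frozen.  This is the inductive counterpart of the transductive
#' training run; with \code{epochs = 0} the random initialization is
#' returned unchanged (degenerate case, documented).
#'
#' @param model a trained [EmbeddingModel-class].
#' @param sentence a [KmerSentence-class], a character vector of
#'   k-mers, or a single DNA sequence string (tokenized with the
#'   model's k and s).  Must have more than m tokens.
#' @param epochs integer SGD passes (default: the model's training
#'   epochs).
#' @param alpha initial learning rate (default: the model's).
#' @param seed integer seed for the initialization.
#' @return A d-dimensional numeric vector.
#' @export
inferVector <- function(model, sentence, epochs = NULL, alpha = NULL,
                        seed = 1L) {
    stopifnot(is(model, "EmbeddingModel"))
    cfg <- model@config
    if (is.character(sentence) && length(sentence) == 1L &&
        nchar(sentence) > cfg@k && grepl("^[ACGTNacgtn]+$", sentence))
        sentence <- tokenize(sentence, k = cfg@k, s = cfg@s,
                             docId = "query")@kmers
    idx <- encodeTokens(model, sentence)
    if (length(idx) <= cfg@m)
        stop("sentence has T = ", length(idx),
             " tokens; inference needs T > m = ", cfg@m, call. = FALSE)
    epochs <- as.integer(epochs %||% cfg@epochs)
    alpha <- alpha %||% cfg@alpha
    d <- cfg@d
    dv <- withSeed(seed, matrix(runif(d, -0.5 / d, 0.5 / d), nrow = d))
    if (epochs == 0L)
        return(as.vector(dv))
    hierarchical <- cfg@mode == "hierarchical"
    fit <- cppTrainPVDM(list(idx), 1L, model@wordVectors, dv,
                        if (hierarchical) model@nodeVectors else model@softmaxU,
                        model@softmaxB,
                        model@tree@codes, model@tree@paths, hierarchical,
                        cfg@composition == "concat",
                        cfg@m, epochs, alpha, cfg@alphaMin,
                        as.integer(seed), TRUE)
    as.vector(fit$docVectors)
}

#' Write / read an embedding model
#'
#' Serializes the full model (vocabulary, counts, hyper-parameters,
#' word-vector and document-vector matrices, Huffman tree or softmax
#' parameters) to a versioned container.  The round trip is lossless.
#'
#' @param model an [EmbeddingModel-class].
#' @param path file path.
#' @return \code{writeEmbeddingModel} returns \code{path} invisibly;
#'   \code{readEmbeddingModel} returns the model.
#' @export
writeEmbeddingModel <- function(model, path) {
    stopifnot(is(model, "EmbeddingModel"))
    saveRDS(list(format = "epivec-model", version = model@version,
                 model = model), path)
    invisible(path)
}

#' @rdname writeEmbeddingModel
#' @export
readEmbeddingModel <- function(path) {
    x <- readRDS(path)
    if (!is.list(x) || !identical(x$format, "epivec-model"))
        stop("not an epivec model file: ", path, call. = FALSE)
    if (!identical(x$version, "epivec-model-1"))
        stop("unsupported model version '", x$version, "'", call. = FALSE)
    validObject(x$model)
    x$model
}
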
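#' Class \code{KmerVocabulary}
#'
#' Bijection between observed k-mer tokens and dense integer indices
#' \code{1..V}, with corpus frequencies.  Windows containing non-ACGT
#' characters are pooled into a reserved UNK token that is tracked
#' separately (slot \code{unkCount}); UNK never enters the Huffman tree
#' and is never a prediction target, but keeps its own context vector so
#' that token counts of a sentence are unaffected by ambiguous bases.
#'
#' @slot tokens character vector of observed k-mers (uppercase ACGT),
#'   lexicographically sorted; the token with index \code{i} is
#'   \code{tokens[i]}.
#' @slot counts integer vector parallel to \code{tokens}; corpus
#'   frequency of each token (all \eqn{\ge 1}).
#' @slot k integer, word length in bp.
#' @slot unkCount integer, number of UNK (ambiguous) windows observed.
#' @aliases KmerVocabulary
#' @seealso [buildVocabulary()]
#' @exportClass KmerVocabulary
setClass("KmerVocabulary",
    slots = c(tokens = "character", counts = "integer", k = "integer",
              unkCount = "integer"))

setValidity("KmerVocabulary", function(object) {
    msg <- NULL
    if (length(object@tokens) != length(object@counts))
        msg <- c(msg, "tokens and counts must be parallel")
    if (anyDuplicated(object@tokens))
        msg <- c(msg, "tokens must be unique")
    if (length(object@counts) && any(object@counts < 1L))
        msg <- c(msg, "observed token counts must be >= 1")
    if (length(object@tokens) && any(nchar(object@tokens) != object@k))
        msg <- c(msg, "all tokens must have nchar == k")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{KmerSentence}
#'
#' One DNA sequence rendered as an ordered sentence of k-mer tokens.
#' Tokens are stored as integer indices into a [KmerVocabulary-class]
#' (0 marks the reserved UNK token) or, when tokenized without a
#' vocabulary, as the raw k-mer strings kept in \code{kmers}.
#'
#' @slot docId document identifier, unique within a corpus.
#' @slot tokens integer indices (0 = UNK); length is the token count
#'   \eqn{T = \lfloor (L-k)/s \rfloor + 1} for a sequence of L bp.
#' @slot kmers character k-mer strings aligned to \code{tokens}
#'   ("UNK" where a window contained non-ACGT characters).
#' @slot k,s integers, word length and stride in bp.
#' @aliases KmerSentence
#' @seealso [tokenize()]
#' @exportClass KmerSentence
setClass("KmerSentence",
    slots = c(docId = "character", tokens = "integer", kmers = "character",
              k = "integer", s = "integer"))

setValidity("KmerSentence", function(object) {
    if (length(object@tokens) && length(object@kmers) &&
        length(object@tokens) != length(object@kmers))
        return("tokens and kmers must be parallel")
    TRUE
})

#' Class \code{KmerCorpus}
#'
#' A set of tokenized sequences sharing one vocabulary: the unit on
#' which an embedding model is trained.  Enhancers and promoters are
#' kept in separate corpora and embedded separately.
#'
#' @slot sentences list of integer vectors (token indices, 0 = UNK),
#'   one per document, named by document id.
#' @slot docIds character vector of document ids (unique).
#' @slot roles character vector parallel to \code{docIds}
#'   ("enhancer" or "promoter").
#' @slot vocabulary a [KmerVocabulary-class].
#' @slot k,s integers, tokenization parameters.
#' @aliases KmerCorpus
#' @seealso [kmerCorpus()]
#' @exportClass KmerCorpus
setClass("KmerCorpus",
    slots = c(sentences = "list", docIds = "character", roles = "character",
              vocabulary = "KmerVocabulary", k = "integer", s = "integer"))

setValidity("KmerCorpus", function(object) {
    msg <- NULL
    if (length(object@sentences) != length(object@docIds))
        msg <- c(msg, "one sentence per document id required")
    if (anyDuplicated(object@docIds))
        msg <- c(msg, "document ids must be unique")
    V <- length(object@vocabulary@tokens)
    bad <- vapply(object@sentences, function(x)
        length(x) && (min(x) < 0L || max(x) > V), logical(1))
    if (any(bad))
        msg <- c(msg, "token indices must lie in [0, V]")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{HuffmanTree}
#'
#' Binary Huffman coding of a vocabulary, used as the output structure
#' of the hierarchical softmax: frequent tokens receive short codes and
#' are reached by short root paths.  A vocabulary of V tokens yields
#' exactly V - 1 internal nodes; each leaf stores its 0/1 code and the
#' ordered internal nodes on its root path.
#'
#' @slot codes list of integer 0/1 vectors, one per token.
#' @slot paths list of integer vectors, one per token: indices
#'   (1..V-1) of the internal nodes from the root down to the leaf's
#'   parent; same length as the code.
#' @slot nNodes integer, number of internal nodes (V - 1).
#' @slot counts integer leaf counts the tree was built from.
#' @aliases HuffmanTree
#' @seealso [buildHuffman()]
#' @exportClass HuffmanTree
setClass("HuffmanTree",
    slots = c(codes = "list", paths = "list", nNodes = "integer",
              counts = "integer"))

setValidity("HuffmanTree", function(object) {
    msg <- NULL
    V <- length(object@codes)
    if (length(object@paths) != V)
        msg <- c(msg, "codes and paths must be parallel")
    if (V >= 2L && object@nNodes != V - 1L)
        msg <- c(msg, "a binary Huffman tree over V leaves has V-1 internal nodes")
    cl <- lengths(object@codes)
    if (any(cl != lengths(object@paths)))
        msg <- c(msg, "each code must align with its root path")
    if (V >= 2L && abs(sum(2^(-cl)) - 1) > 1e-9)
        msg <- c(msg, "Kraft sum over leaves must equal 1")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{TrainConfig}
#'
#' Hyper-parameters of the paragraph-vector training stage.  Defaults
#' are the setting used throughout: word length k = 6, stride s = 1,
#' context window m = 20, embedding dimension d = 100.  The number of
#' epochs and the learning-rate schedule (linear decay from
#' \code{alpha} to \code{alphaMin}) are exposed and logged.
#'
#' @slot k,s,m,d integers: word length, stride, context window length,
#'   embedding dimension.
#' @slot epochs integer, full passes over the corpus.
#' @slot alpha,alphaMin numeric, initial and floor learning rate of the
#'   linear decay schedule.
#' @slot mode \code{"hierarchical"} (Huffman-tree softmax, the training
#'   default) or \code{"exact"} (dense softmax \eqn{y = b + Uh}; only
#'   practical for small vocabularies, used as an oracle).
#' @slot composition \code{"mean"} (default: word vectors and document
#'   vector averaged into one shared d-space, the composition the
#'   attention weighting presumes) or \code{"concat"} (the vectors
#'   concatenated into \eqn{R^{(m+1)d}}).
#' @slot seed integer seed governing initialization and epoch order.
#' @aliases TrainConfig
#' @seealso [trainConfig()], [trainEmbedding()]
#' @exportClass TrainConfig
setClass("TrainConfig",
    slots = c(k = "integer", s = "integer", m = "integer", d = "integer",
              epochs = "integer", alpha = "numeric", alphaMin = "numeric",
              mode = "character", composition = "character",
              seed = "integer"))

setValidity("TrainConfig", function(object) {
    msg <- NULL
    for (nm in c("k", "s", "m", "d"))
        if (slot(object, nm) < 1L)
            msg <- c(msg, paste0(nm, " must be a positive integer"))
    if (object@epochs < 0L)
        msg <- c(msg, "epochs must be >= 0 (0 = return the initialization)")
    if (object@alpha <= 0 || object@alphaMin <= 0 ||
        object@alphaMin > object@alpha)
        msg <- c(msg, "need 0 < alphaMin <= alpha")
    if (!object@mode %in% c("hierarchical", "exact"))
        msg <- c(msg, "mode must be 'hierarchical' or 'exact'")
    if (!object@composition %in% c("mean", "concat"))
        msg <- c(msg, "composition must be 'mean' or 'concat'")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{EmbeddingModel}
#'
#' A trained distributed-memory paragraph-vector model: one d-dimensional
#' word vector per vocabulary token (plus the UNK context vector), one
#' d-dimensional document vector per training sequence, and the output
#' parameters of the chosen softmax backend.  In hierarchical mode the
#' output parameters are one (m+1)d-dimensional vector per internal
#' Huffman node; in exact mode they are the dense matrix U and bias b of
#' \eqn{y = b + Uh}.
#'
#' @slot wordVectors numeric matrix, d x (V+1); column V+1 is the UNK
#'   context vector.
#' @slot docVectors numeric matrix, d x N, columns named by document id.
#'   These columns are the sequence embedding features.
#' @slot nodeVectors numeric matrix, hdim x (V-1) hierarchical-softmax
#'   node parameters, where hdim = d under the mean composition and
#'   (m+1)d under concatenation (0 x 0 in exact mode).
#' @slot softmaxU numeric matrix, hdim x V, transpose of U
#'   (0 x 0 in hierarchical mode).
#' @slot softmaxB numeric length-V bias b (length 0 in hierarchical
#'   mode).
#' @slot tree the [HuffmanTree-class] (empty in exact mode).
#' @slot vocabulary the [KmerVocabulary-class].
#' @slot config the [TrainConfig-class] the model was trained with.
#' @slot version serialization format version string.
#' @aliases EmbeddingModel
#' @seealso [trainEmbedding()], [docVector()], [inferVector()]
#' @exportClass EmbeddingModel
setClass("EmbeddingModel",
    slots = c(wordVectors = "matrix", docVectors = "matrix",
              nodeVectors = "matrix", softmaxU = "matrix",
              softmaxB = "numeric", tree = "HuffmanTree",
              vocabulary = "KmerVocabulary", config = "TrainConfig",
              version = "character"))

setValidity("EmbeddingModel", function(object) {
    msg <- NULL
    d <- object@config@d
    V <- length(object@vocabulary@tokens)
    if (nrow(object@wordVectors) != d || ncol(object@wordVectors) != V + 1L)
        msg <- c(msg, "wordVectors must be d x (V+1)")
    if (nrow(object@docVectors) != d)
        msg <- c(msg, "docVectors must have d rows")
    if (is.null(colnames(object@docVectors)) && ncol(object@docVectors) > 0L)
        msg <- c(msg, "docVectors columns must be named by document id")
    if (!all(is.finite(object@wordVectors)) ||
        !all(is.finite(object@docVectors)))
        msg <- c(msg, "vectors must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{PairDataset}
#'
#' Labelled enhancer-promoter pairs, with optional genomic distances
#' (for distance-binned negative matching) and an optional per-pair
#' matrix of external experimental features used by the combined-features
#' classifier mode.
#'
#' @slot pairs data.frame with columns \code{enh_id}, \code{prom_id},
#'   \code{label} (0/1) and optionally \code{distance} (bp).
#' @slot external numeric matrix with one row per pair (0 x 0 when no
#'   external features are attached).
#' @aliases PairDataset
#' @seealso [loadPairs()], [generatePairs()]
#' @exportClass PairDataset
setClass("PairDataset",
    slots = c(pairs = "data.frame", external = "matrix"))

setValidity("PairDataset", function(object) {
    msg <- NULL
    need <- c("enh_id", "prom_id", "label")
    if (!all(need %in% names(object@pairs)))
        msg <- c(msg, "pairs needs columns enh_id, prom_id, label")
    else if (!all(object@pairs$label %in% c(0L, 1L)))
        msg <- c(msg, "labels must be binary 0/1")
    if (nrow(object@external) > 0L &&
        nrow(object@external) != nrow(object@pairs))
        msg <- c(msg, "external features must have one row per pair")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{PairFeatures}
#'
#' The supervised-stage design matrix: one row per pair, formed by
#' concatenating the enhancer embedding, the promoter embedding and any
#' external features (F = 2d, or 2d + ncol(external); 200 columns under
#' the default d = 100).
#'
#' @slot features numeric matrix, pairs x F, no missing values.
#' @slot labels integer 0/1 vector aligned to rows.
#' @slot pairIds data.frame with \code{enh_id}, \code{prom_id} aligned
#'   to rows.
#' @aliases PairFeatures
#' @seealso [assembleFeatures()]
#' @exportClass PairFeatures
setClass("PairFeatures",
    slots = c(features = "matrix", labels = "integer", pairIds = "data.frame"))

setValidity("PairFeatures", function(object) {
    msg <- NULL
    if (nrow(object@features) != length(object@labels))
        msg <- c(msg, "one label per feature row required")
    if (anyNA(object@features))
        msg <- c(msg, "features must not contain missing values")
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be binary 0/1")
    if (is.null(msg)) TRUE else msg
})

#' Class \code{GBRTConfig}
#'
#' Hyper-parameters of the gradient-boosted-regression-trees classifier:
#' learning rate \code{alpha}, number of trees \code{nTrees} and tree
#' depth \code{depth}.  Defaults alpha = 1e-3, nTrees = 4000,
#' depth = 25.
#'
#' @slot alpha numeric learning rate (> 0).
#' @slot nTrees integer number of boosting rounds (>= 1).
#' @slot depth integer maximum tree depth (>= 1).
#' @aliases GBRTConfig
#' @seealso [gbrtConfig()], [trainClassifier()]
#' @exportClass GBRTConfig
setClass("GBRTConfig",
    slots = c(alpha = "numeric", nTrees = "integer", depth = "integer"))

setValidity("GBRTConfig", function(object) {
    if (object@alpha <= 0) return("alpha must be > 0")
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    if (object@depth < 1L) return("depth must be >= 1")
    TRUE
})

#' Class \code{CVReport}
#'
#' Result of a stratified k-fold cross-validation: per-fold F1, auROC
#' and auPRC with their means and standard deviations, plus the held-out
#' prediction score of every pair.
#'
#' @slot metrics data.frame with columns \code{fold}, \code{f1},
#'   \code{auroc}, \code{auprc}; one row per fold.
#' @slot predictions data.frame with columns \code{enh_id},
#'   \code{prom_id}, \code{label}, \code{score}, \code{fold}.
#' @slot nFolds integer number of folds.
#' @aliases CVReport
#' @seealso [crossValidate()]
#' @exportClass CVReport
setClass("CVReport",
    slots = c(metrics = "data.frame", predictions = "data.frame",
              nFolds = "integer"))

setValidity("CVReport", function(object) {
    if (nrow(object@metrics) != object@nFolds)
        return("metrics must have one row per fold")
    TRUE
})

#' Class \code{AttentionProfile}
#'
#' Per-token importance weights of one sequence: the softmax, over the
#' sentence's own tokens, of the dot products between the sequence's
#' document vector and each token's word vector.  Weights are positive
#' and sum to 1.
#'
#' @slot docId document id.
#' @slot kmers character k-mer per token position.
#' @slot positions integer 1-based bp start of each token window.
#' @slot weights numeric normalized importance weights.
#' @aliases AttentionProfile
#' @seealso [attentionWeights()], [topKmers()]
#' @exportClass AttentionProfile
setClass("AttentionProfile",
    slots = c(docId = "character", kmers = "character",
              positions = "integer", weights = "numeric"))

setValidity("AttentionProfile", function(object) {
    msg <- NULL
    n <- length(object@weights)
    if (length(object@kmers) != n || length(object@positions) != n)
        msg <- c(msg, "kmers, positions and weights must be parallel")
    if (n == 0L)
        msg <- c(msg, "empty profile (T = 0) is not valid")
    else {
        if (any(object@weights <= 0))
            msg <- c(msg, "weights must be strictly positive")
        if (abs(sum(object@weights) - 1) > 1e-8)
            msg <- c(msg, "weights must sum to 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Class \code{SyntheticSpec}
#'
#' Full description of a synthetic enhancer-promoter benchmark with
#' known ground truth.  Sequences are i.i.d. background DNA with planted
#' position-weight-matrix (PWM) motifs; each sequence belongs to one
#' motif class per role, and the interaction probability of a pair is a
#' function of its (enhancer class, promoter class) combination.
#' Elements receive coordinates on one synthetic chromosome so that all
#' pairs have genomic distances of at least \code{minDistance} (10 kb by
#' default), and negatives are subsampled within distance bins to match
#' the positive distance distribution, one negative per positive by
#' default.
#'
#' @slot nEnhancers,nPromoters integer corpus sizes.
#' @slot enhancerLength,promoterLength integer length-2 vectors, the
#'   uniform bp length range per role.
#' @slot enhancerMotifs,promoterMotifs named lists of PWMs (4 x width
#'   probability matrices, rows A,C,G,T; columns sum to 1), one per
#'   motif class.
#' @slot enhancerClassProbs,promoterClassProbs named numeric vectors,
#'   probability that a sequence belongs to each motif class.
#' @slot copyRange integer length-2, uniform range of planted motif
#'   copies per sequence.
#' @slot interactionProb numeric matrix, enhancer classes x promoter
#'   classes: probability that a candidate pair with that class
#'   combination interacts.
#' @slot baseComposition numeric length-4 (A,C,G,T) background base
#'   probabilities.
#' @slot nCandidatePairs integer number of candidate pairs drawn before
#'   labelling.
#' @slot minDistance,maxDistance numeric bp bounds on pair distances.
#' @slot chromLength numeric bp length of the synthetic chromosome.
#' @slot nBins integer number of distance bins for negative matching.
#' @slot negativesPerPositive integer negatives sampled per positive.
#' @slot seed integer default seed.
#' @aliases SyntheticSpec
#' @seealso [syntheticSpec()], [generateSequences()], [generatePairs()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    slots = c(nEnhancers = "integer", nPromoters = "integer",
              enhancerLength = "integer", promoterLength = "integer",
              enhancerMotifs = "list", promoterMotifs = "list",
              enhancerClassProbs = "numeric", promoterClassProbs = "numeric",
              copyRange = "integer", interactionProb = "matrix",
              baseComposition = "numeric", nCandidatePairs = "integer",
              minDistance = "numeric", maxDistance = "numeric",
              chromLength = "numeric", nBins = "integer",
              negativesPerPositive = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- NULL
    okPWM <- function(p) is.matrix(p) && nrow(p) == 4L &&
        all(p >= 0) && all(abs(colSums(p) - 1) < 1e-6)
    if (!all(vapply(object@enhancerMotifs, okPWM, logical(1))) ||
        !all(vapply(object@promoterMotifs, okPWM, logical(1))))
        msg <- c(msg, "PWMs must be 4 x width with columns summing to 1")
    if (abs(sum(object@enhancerClassProbs) - 1) > 1e-6 ||
        abs(sum(object@promoterClassProbs) - 1) > 1e-6)
        msg <- c(msg, "class probabilities must sum to 1")
    if (any(object@interactionProb < 0) || any(object@interactionProb > 1))
        msg <- c(msg, "interaction probabilities must lie in [0, 1]")
    if (!identical(dim(object@interactionProb),
                   c(length(object@enhancerMotifs),
                     length(object@promoterMotifs))))
        msg <- c(msg, "interactionProb must be enhancer classes x promoter classes")
    if (abs(sum(object@baseComposition) - 1) > 1e-6)
        msg <- c(msg, "base composition must sum to 1")
    if (object@minDistance >= object@maxDistance)
        msg <- c(msg, "minDistance must be < maxDistance")
    if (is.null(msg)) TRUE else msg
})
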
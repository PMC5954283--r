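## pair_classifier: per-pair feature assembly, gradient boosted trees,
## stratified cross-validation and metrics.

#' Gradient-boosted-trees configuration
#'
#' Defaults are learning rate alpha = 1e-3, nTrees = 4000 boosting
#' rounds and tree depth 25.
#'
#' @param alpha numeric learning rate (> 0).
#' @param nTrees integer boosting rounds.
#' @param depth integer maximum tree depth.
#' @return A [GBRTConfig-class].
#' @export
gbrtConfig <- function(alpha = 1e-3, nTrees = 4000L, depth = 25L) {
    new("GBRTConfig", alpha = alpha, nTrees = as.integer(nTrees),
        depth = as.integer(depth))
}

#' Assemble per-pair feature vectors from two embedding models
#'
#' Each pair's row is the concatenation of its enhancer embedding, its
#' promoter embedding and (optionally) the pair's external experimental
#' features: F = 2d columns, 200 under the default d = 100, plus the
#' external width in combined mode.  Row order equals pair order.
#'
#' @param dataset a [PairDataset-class].
#' @param enhModel,promModel trained [EmbeddingModel-class] objects for
#'   the enhancer and the promoter corpus.
#' @param external optional per-pair numeric matrix; defaults to the
#'   dataset's attached external features, if any.
#' @return A [PairFeatures-class].
#' @export
assembleFeatures <- function(dataset, enhModel, promModel,
                             external = externalFeatures(dataset)) {
    stopifnot(is(dataset, "PairDataset"),
              is(enhModel, "EmbeddingModel"),
              is(promModel, "EmbeddingModel"))
    df <- pairTable(dataset)
    missE <- setdiff(df$enh_id, colnames(docVectors(enhModel)))
    if (length(missE))
        stop("no enhancer vector for: ",
             paste(head(missE, 5L), collapse = ", "), call. = FALSE)
    missP <- setdiff(df$prom_id, colnames(docVectors(promModel)))
    if (length(missP))
        stop("no promoter vector for: ",
             paste(head(missP, 5L), collapse = ", "), call. = FALSE)
    X <- cbind(t(docVectors(enhModel)[, df$enh_id, drop = FALSE]),
               t(docVectors(promModel)[, df$prom_id, drop = FALSE]))
    colnames(X) <- c(paste0("enh_", seq_len(enhModel@config@d)),
                     paste0("prom_", seq_len(promModel@config@d)))
    if (!is.null(external)) {
        external <- as.matrix(external)
        if (nrow(external) != nrow(df))
            stop("external feature rows (", nrow(external),
                 ") must match pair count (", nrow(df), ")", call. = FALSE)
        colnames(external) <- colnames(external) %||%
            paste0("ext_", seq_len(ncol(external)))
        X <- cbind(X, external)
    }
    rownames(X) <- NULL
    new("PairFeatures", features = X, labels = as.integer(df$label),
        pairIds = df[, c("enh_id", "prom_id")])
}

#' Train the gradient-boosted-trees pair classifier
#'
#' Fits a gradient-boosted ensemble of depth-D regression trees with
#' logistic loss: per-tree scores are summed and passed through the
#' logistic function to give the pair's interaction probability.
#' Implemented with \pkg{xgboost}, single-threaded so repeated runs are
#' deterministic.
#'
#' @param features numeric matrix (pairs x F) or a
#'   [PairFeatures-class].
#' @param labels integer 0/1 vector (ignored when \code{features} is a
#'   PairFeatures).
#' @param config a [GBRTConfig-class].
#' @return An \code{xgb.Booster}.
#' @export
trainClassifier <- function(features, labels = NULL, config = gbrtConfig()) {
    if (is(features, "PairFeatures")) {
        labels <- features@labels
        features <- features@features
    }
    stopifnot(is.matrix(features), length(labels) == nrow(features))
    if (length(unique(labels)) < 2L)
        stop("training labels contain a single class", call. = FALSE)
    dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1L)
    ## histogram split finding with 64 quantile bins: ample resolution
    ## for a few hundred pairs, and much faster than exact enumeration
    ## over 4000 boosting rounds
    xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = config@alpha, max_depth = config@depth,
                      tree_method = "hist", max_bin = 64L,
                      nthread = 1L, seed = 1L),
        data = dtrain, nrounds = config@nTrees, verbose = 0L)
}

#' Predict pair interaction scores
#'
#' @param classifier an \code{xgb.Booster} from [trainClassifier()].
#' @param features numeric matrix or [PairFeatures-class].
#' @return Numeric vector of interaction probabilities in (0, 1).
#' @export
predictPairs <- function(classifier, features) {
    if (is(features, "PairFeatures")) features <- features@features
    predict(classifier, xgboost::xgb.DMatrix(features, nthread = 1L))
}

#' Stratified fold assignment
#'
#' Partitions samples into \code{nFolds} folds whose class counts
#' differ from exact proportionality by at most one sample, by
#' shuffling each class independently and dealing its members out
#' round-robin with a rotating fold offset.  Deterministic for a given
#' seed.
#'
#' @param labels integer 0/1 vector.
#' @param nFolds integer number of folds (default 10); must not exceed
#'   the minority-class count.
#' @param seed integer seed.
#' @return Integer vector of fold ids in \code{1..nFolds}, aligned to
#'   \code{labels}.
#' @export
stratifiedFolds <- function(labels, nFolds = 10L, seed = 1L) {
    nFolds <- as.integer(nFolds)
    tab <- table(labels)
    if (nFolds > min(tab))
        stop("nFolds = ", nFolds, " exceeds the minority-class count (",
             min(tab), ")", call. = FALSE)
    fold <- integer(length(labels))
    withSeed(seed, {
        offset <- 0L
        for (cl in names(tab)) {
            idx <- sample(which(labels == as.integer(cl)))
            fold[idx] <- ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
            offset <- offset + length(idx) %% nFolds
        }
    })
    fold
}

#' F1 score
#'
#' Harmonic mean of precision p = TP/(TP+FP) and recall
#' r = TP/(TP+FN): F1 = 2rp/(r+p), best at 1, worst at 0; defined as 0
#' when p + r = 0.
#'
#' @param predictions binary 0/1 predicted classes.
#' @param labels binary 0/1 true classes.
#' @return Numeric in [0, 1].
#' @examples
#' f1Score(c(1, 1, 1, 0), c(1, 1, 0, 1))   # TP=2 FP=1 FN=1 -> 2/3
#' @export
f1Score <- function(predictions, labels) {
    if (length(predictions) != length(labels))
        stop("predictions and labels differ in length", call. = FALSE)
    tp <- sum(predictions == 1L & labels == 1L)
    fp <- sum(predictions == 1L & labels == 0L)
    fn <- sum(predictions == 0L & labels == 1L)
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) tp / (tp + fn) else 0
    if (p + r == 0) 0 else 2 * r * p / (r + p)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation: the probability that a
#' random positive scores above a random negative, ties counted half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 true classes.
#' @return Numeric in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("auROC needs both classes", call. = FALSE)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: AP = sum over descending-score
#' thresholds of (recall increment) x (precision at that threshold),
#' with tied scores handled as one threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 true classes.
#' @return Numeric in (0, 1].
#' @export
prAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1L)
    if (nPos == 0L)
        stop("auPRC needs at least one positive", call. = FALSE)
    o <- order(scores, decreasing = TRUE)
    lab <- labels[o]; sc <- scores[o]
    tp <- cumsum(lab == 1L)
    fp <- cumsum(lab == 0L)
    ## evaluate only at the last index of each tied-score block
    last <- c(sc[-1] != sc[-length(sc)], TRUE)
    tp <- tp[last]; fp <- fp[last]
    prec <- tp / (tp + fp)
    rec <- tp / nPos
    sum(diff(c(0, rec)) * prec)
}

#' Stratified k-fold cross-validation of the pair classifier
#'
#' Splits the pairs into stratified folds, trains the classifier on
#' the training folds only and scores the held-out fold, repeating
#' until every fold has served as test data exactly once.  Reports
#' per-fold F1 (decision threshold 0.5), auROC and auPRC.  The single
#' transductive embedding run supplies the features of all pairs (the
#' unsupervised stage sees every sequence, as in transductive
#' deployment); see [crossValidateStrict()] for the inductive variant
#' that re-infers held-out document vectors.
#'
#' @param features a [PairFeatures-class].
#' @param config a [GBRTConfig-class].
#' @param nFolds integer number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return A [CVReport-class].
#' @export
crossValidate <- function(features, config = gbrtConfig(), nFolds = 10L,
                          seed = 1L) {
    stopifnot(is(features, "PairFeatures"))
    labels <- features@labels
    fold <- stratifiedFolds(labels, nFolds = nFolds, seed = seed)
    X <- features@features
    d <- ncol(X)
    metrics <- data.frame(fold = seq_len(nFolds), f1 = NA_real_,
                          auroc = NA_real_, auprc = NA_real_)
    preds <- data.frame(features@pairIds, label = labels,
                        score = NA_real_, fold = fold)
    for (f in seq_len(nFolds)) {
        train <- fold != f
        clf <- trainClassifier(X[train, , drop = FALSE], labels[train],
                               config)
        Xtest <- X[!train, , drop = FALSE]
        sc <- predictPairs(clf, Xtest)
        preds$score[!train] <- sc
        metrics$f1[f] <- f1Score(as.integer(sc >= 0.5), labels[!train])
        metrics$auroc[f] <- rocAuc(sc, labels[!train])
        metrics$auprc[f] <- prAuc(sc, labels[!train])
    }
    new("CVReport", metrics = metrics, predictions = preds,
        nFolds = as.integer(nFolds))
}

#' Strict cross-validation with re-inferred test vectors
#'
#' Variant of [crossValidate()] that mirrors an inductive deployment:
#' for every fold, the document vectors of held-out enhancers and
#' promoters are re-inferred from their token sentences with the word
#' vectors and softmax parameters frozen, instead of reusing the
#' vectors from the joint unsupervised run.
#'
#' @param dataset a [PairDataset-class].
#' @param enhCorpus,promCorpus the [KmerCorpus-class] objects.
#' @param enhModel,promModel trained [EmbeddingModel-class] objects.
#' @param config a [GBRTConfig-class].
#' @param nFolds,seed as in [crossValidate()].
#' @param external optional per-pair external feature matrix.
#' @return A [CVReport-class].
#' @export
crossValidateStrict <- function(dataset, enhCorpus, promCorpus,
                                enhModel, promModel,
                                config = gbrtConfig(), nFolds = 10L,
                                seed = 1L,
                                external = externalFeatures(dataset)) {
    features <- assembleFeatures(dataset, enhModel, promModel, external)
    labels <- features@labels
    fold <- stratifiedFolds(labels, nFolds = nFolds, seed = seed)
    X <- features@features
    df <- pairTable(dataset)
    dE <- enhModel@config@d
    metrics <- data.frame(fold = seq_len(nFolds), f1 = NA_real_,
                          auroc = NA_real_, auprc = NA_real_)
    preds <- data.frame(features@pairIds, label = labels,
                        score = NA_real_, fold = fold)
    inferredE <- new.env(parent = emptyenv())
    inferredP <- new.env(parent = emptyenv())
    inferOne <- function(model, corpus, id, cache) {
        if (!is.null(cache[[id]])) return(cache[[id]])
        v <- inferVector(model, corpus@sentences[[id]],
                         seed = childSeed(seed, match(id, corpus@docIds)))
        cache[[id]] <- v
        v
    }
    for (f in seq_len(nFolds)) {
        train <- fold != f
        clf <- trainClassifier(X[train, , drop = FALSE], labels[train],
                               config)
        testIdx <- which(!train)
        Xtest <- X[testIdx, , drop = FALSE]
        for (r in seq_along(testIdx)) {
            i <- testIdx[r]
            Xtest[r, seq_len(dE)] <-
                inferOne(enhModel, enhCorpus, df$enh_id[i], inferredE)
            Xtest[r, dE + seq_len(promModel@config@d)] <-
                inferOne(promModel, promCorpus, df$prom_id[i], inferredP)
        }
        sc <- predictPairs(clf, Xtest)
        preds$score[testIdx] <- sc
        metrics$f1[f] <- f1Score(as.integer(sc >= 0.5), labels[testIdx])
        metrics$auroc[f] <- rocAuc(sc, labels[testIdx])
        metrics$auprc[f] <- prAuc(sc, labels[testIdx])
    }
    new("CVReport", metrics = metrics, predictions = preds,
        nFolds = as.integer(nFolds))
}
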
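test_that("F1 matches hand-computed confusion counts", {
    ## TP=2, FP=1, FN=1 -> p = r = 2/3 -> F1 = 2/3
    expect_equal(f1Score(c(1, 1, 1, 0), c(1, 1, 0, 1)), 2 / 3)
    ## p = r implies F1 = p (harmonic mean of equals)
    expect_equal(f1Score(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.5)
    expect_identical(f1Score(c(1, 1), c(1, 1)), 1)
    expect_identical(f1Score(c(0, 0), c(1, 1)), 0)
    expect_identical(f1Score(c(1, 1), c(0, 0)), 0)
    expect_error(f1Score(c(1, 0), c(1, 0, 1)), "length")
})

test_that("F1 is bounded by max(p, r) and the arithmetic mean", {
    withr::with_seed(4, {
        for (i in 1:50) {
            n <- 40
            pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
            lab <- rbinom(n, 1, 0.5)
            tp <- sum(pred & lab); fp <- sum(pred & !lab)
            fn <- sum(!pred & lab)
            p <- if (tp + fp) tp / (tp + fp) else 0
            r <- if (tp + fn) tp / (tp + fn) else 0
            f1 <- f1Score(pred, lab)
            expect_lte(f1, max(p, r) + 1e-12)
            expect_lte(f1, (p + r) / 2 + 1e-12)
        }
    })
})

test_that("stratified folds preserve class balance exactly", {
    labels <- rep(c(1L, 0L), each = 10)
    fold <- stratifiedFolds(labels, 10, seed = 3)
    expect_setequal(fold, 1:10)
    for (f in 1:10) {
        expect_identical(sum(fold == f & labels == 1L), 1L)
        expect_identical(sum(fold == f & labels == 0L), 1L)
    }
    ## partition: union is the index set, folds are disjoint
    expect_length(fold, length(labels))
    ## reproducible, and sensitive to the seed
    expect_identical(fold, stratifiedFolds(labels, 10, seed = 3))
    labels2 <- rep(c(1L, 0L), c(33, 44))
    f2 <- stratifiedFolds(labels2, 10, seed = 1)
    perFold <- table(f2, labels2)
    expect_lte(diff(range(perFold[, "1"])), 1)
    expect_lte(diff(range(perFold[, "0"])), 1)
    expect_error(stratifiedFolds(rep(c(0L, 1L), c(30, 5)), 10),
                 "minority")
})

test_that("auROC equals the brute-force pair-ordering fraction", {
    withr::with_seed(6, {
        for (i in 1:20) {
            n <- sample(10:30, 1)
            lab <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
            sc <- round(runif(n), 2)    # rounding forces ties
            expect_equal(rocAuc(sc, lab), oracleAuc(sc, lab))
        }
    })
    expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auPRC equals an independent threshold-loop computation", {
    withr::with_seed(13, {
        for (i in 1:20) {
            n <- sample(10:30, 1)
            lab <- c(1L, rbinom(n - 1, 1, 0.5))
            sc <- round(runif(n), 2)
            expect_equal(prAuc(sc, lab), oracleAp(sc, lab))
        }
    })
    ## perfect separation gives area 1
    expect_equal(prAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("feature assembly concatenates embeddings in pair order", {
    fxE <- tinyModel(seed = 21)
    fxP <- tinyModel(seed = 22)
    prom <- fxP$model
    colnames(prom@docVectors) <- sub("ENHANCER", "PROMOTER",
                                     colnames(prom@docVectors))
    df <- data.frame(enh_id = c("ENHANCER_1", "ENHANCER_3", "ENHANCER_2"),
                     prom_id = c("PROMOTER_2", "PROMOTER_1", "PROMOTER_2"),
                     label = c(1L, 0L, 1L))
    ds <- new("PairDataset", pairs = df,
              external = matrix(numeric(0), 0, 0))
    ft <- assembleFeatures(ds, fxE$model, prom)
    expect_identical(dim(ft@features), c(3L, 16L))   # 2d with d = 8
    expect_equal(ft@features[2, 1:8],
                 setNames(docVector(fxE$model, "ENHANCER_3"),
                          paste0("enh_", 1:8)))
    ## permuting the pair rows permutes the feature rows identically
    ds2 <- new("PairDataset", pairs = df[c(3, 1, 2), ],
               external = matrix(numeric(0), 0, 0))
    ft2 <- assembleFeatures(ds2, fxE$model, prom)
    expect_equal(unname(ft2@features), unname(ft@features[c(3, 1, 2), ]))
    ## external features widen the matrix
    ext <- matrix(runif(6), nrow = 3)
    ft3 <- assembleFeatures(ds, fxE$model, prom, external = ext)
    expect_identical(ncol(ft3@features), 18L)
    expect_error(assembleFeatures(ds, fxE$model, prom,
                                  external = matrix(1, 2, 2)), "match")
    ## a missing vector is reported by id
    bad <- new("PairDataset",
        pairs = data.frame(enh_id = "ENHANCER_99", prom_id = "PROMOTER_1",
                           label = 0L),
        external = matrix(numeric(0), 0, 0))
    expect_error(assembleFeatures(bad, fxE$model, prom), "ENHANCER_99")
})

test_that("the boosted classifier overfits separable toy data", {
    withr::with_seed(31, {
        X <- matrix(rnorm(20 * 4), 20)
        y <- rep(c(0L, 1L), each = 10)
        X[y == 1, 1] <- X[y == 1, 1] + 5
    })
    clf <- trainClassifier(X, y, gbrtConfig(alpha = 0.1, nTrees = 100,
                                            depth = 3))
    sc <- predictPairs(clf, X)
    expect_identical(f1Score(as.integer(sc >= 0.5), y), 1)
    expect_error(trainClassifier(X, rep(1L, 20)), "single class")
})

test_that("classifier training is deterministic", {
    withr::with_seed(32, {
        X <- matrix(rnorm(40 * 6), 40)
        y <- rbinom(40, 1, 0.5)
    })
    cfg <- gbrtConfig(alpha = 0.05, nTrees = 50, depth = 4)
    s1 <- predictPairs(trainClassifier(X, y, cfg), X)
    s2 <- predictPairs(trainClassifier(X, y, cfg), X)
    expect_identical(s1, s2)
})

test_that("cross-validation reports per-fold metrics without leakage", {
    withr::with_seed(41, {
        n <- 60
        X <- matrix(rnorm(n * 6), n)
        y <- rep(c(0L, 1L), each = n / 2)
        X[y == 1, 1] <- X[y == 1, 1] + 4
    })
    ft <- new("PairFeatures", features = X, labels = y,
              pairIds = data.frame(enh_id = paste0("E", 1:n),
                                   prom_id = paste0("P", 1:n)))
    rep <- crossValidate(ft, gbrtConfig(alpha = 0.1, nTrees = 80, depth = 3),
                         nFolds = 5, seed = 2)
    m <- cvMetrics(rep)
    expect_identical(nrow(m), 5L)
    expect_true(all(c("f1", "auroc", "auprc") %in% names(m)))
    expect_false(anyNA(cvPredictions(rep)$score))
    expect_gt(mean(m$f1), 0.8)

    ## leakage probe: a feature that is constant (zero) on every
    ## training row but encodes the label perfectly on fold-1 rows.  A
    ## tree can never split on a constant feature, so fold 1 can reach
    ## perfect separation only if fitting touched its test rows
    fold <- stratifiedFolds(y, 5, seed = 2)
    Xp <- matrix(rnorm(n * 3), n)
    Xp[, 3] <- 0
    Xp[fold == 1, 3] <- y[fold == 1] * 10
    ftp <- new("PairFeatures", features = Xp, labels = y,
               pairIds = ft@pairIds)
    repP <- crossValidate(ftp, gbrtConfig(alpha = 0.1, nTrees = 60,
                                          depth = 3), nFolds = 5, seed = 2)
    expect_lt(cvMetrics(repP)$auroc[1], 0.99)
})

test_that("shuffled labels score near chance", {
    withr::with_seed(55, {
        n <- 80
        X <- matrix(rnorm(n * 10), n)
        y <- sample(rep(c(0L, 1L), each = n / 2))
    })
    ft <- new("PairFeatures", features = X, labels = y,
              pairIds = data.frame(enh_id = paste0("E", 1:n),
                                   prom_id = paste0("P", 1:n)))
    rep <- crossValidate(ft, gbrtConfig(alpha = 0.01, nTrees = 200,
                                        depth = 6), nFolds = 5, seed = 3)
    expect_gt(mean(cvMetrics(rep)$f1), 0.25)
    expect_lt(mean(cvMetrics(rep)$f1), 0.75)
})

test_that("strict mode re-infers held-out vectors and stays predictive", {
    spec <- syntheticSpec(nEnhancers = 80L, nPromoters = 80L,
                          nCandidatePairs = 120L)
    sim <- simulateDataset(spec, seed = 61)
    ce <- kmerCorpus(sim$enhancers)
    cp <- kmerCorpus(sim$promoters, role = "promoter")
    me <- trainEmbedding(ce, trainConfig(seed = 62))
    mp <- trainEmbedding(cp, trainConfig(seed = 63))
    rep <- crossValidateStrict(sim$pairs, ce, cp, me, mp,
                               gbrtConfig(alpha = 0.05, nTrees = 150,
                                          depth = 6),
                               nFolds = 5, seed = 64)
    m <- cvMetrics(rep)
    expect_identical(nrow(m), 5L)
    expect_false(anyNA(m$f1))
    expect_gt(mean(m$auroc), 0.5)
})
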
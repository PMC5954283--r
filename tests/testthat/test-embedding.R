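test_that("vocabulary construction counts tokens correctly", {
    v <- buildVocabulary(list(c("ATGCAA", "TGCAAC", "GCAACA", "CAACAC")),
                         k = 6)
    expect_identical(vocabSize(v), 4L)

    v1 <- buildVocabulary(list(rep("AAA", 5)), k = 3)
    expect_identical(vocabSize(v1), 1L)
    expect_identical(unname(tokenCounts(v1)), 5L)

    withr::with_seed(2, {
        sent <- lapply(1:5, function(i)
            tokenize(randomDNA(60), k = 3, s = 1))
        v2 <- buildVocabulary(sent)
        expect_lte(vocabSize(v2), 64L)
        expect_identical(sum(tokenCounts(v2)),
                         sum(lengths(lapply(sent, slot, "kmers"))))
    })
    expect_error(buildVocabulary(list()), "empty corpus")
})

test_that("next-word distributions sum to one in both softmax modes", {
    for (mode in c("hierarchical", "exact")) {
        for (comp in c("mean", "concat")) {
            fx <- tinyModel(mode = mode, composition = comp, epochs = 2)
            ctx <- fx$model@vocabulary@tokens[1:3]
            p <- nextWordProbability(fx$model, ctx, "ENHANCER_1")
            expect_length(p, vocabSize(fx$model))
            expect_true(all(p > 0 & p < 1))
            expect_equal(sum(p), 1, tolerance = 1e-8)
        }
    }
})

test_that("next-word probability validates context and document", {
    fx <- tinyModel()
    ctx <- fx$model@vocabulary@tokens[1:3]
    expect_error(nextWordProbability(fx$model, ctx[1:2], "ENHANCER_1"),
                 "exactly m")
    expect_error(nextWordProbability(fx$model, ctx, "NOPE"), "unknown")
})

test_that("hierarchical leaf probabilities equal brute-force products", {
    for (comp in c("mean", "concat")) {
        fx <- tinyModel(composition = comp, epochs = 3)
        ctx <- fx$model@vocabulary@tokens[c(2, 5, 9)]
        p <- nextWordProbability(fx$model, ctx, "ENHANCER_3")
        h <- composeH(fx$model, encodeTokens(fx$model, ctx), "ENHANCER_3")
        expect_equal(unname(p), oracleLeafProbs(fx$model, h),
                     tolerance = 1e-10)
        expect_equal(sum(oracleLeafProbs(fx$model, h)), 1, tolerance = 1e-8)
    }
})

test_that("exact-mode distribution equals the manual y = b + Uh softmax", {
    fx <- tinyModel(mode = "exact", epochs = 2)
    ctx <- fx$model@vocabulary@tokens[c(1, 4, 6)]
    p <- nextWordProbability(fx$model, ctx, "ENHANCER_2")
    h <- composeH(fx$model, encodeTokens(fx$model, ctx), "ENHANCER_2")
    y <- as.vector(crossprod(fx$model@softmaxU, h)) + fx$model@softmaxB
    expect_equal(unname(p), unname(exp(y) / sum(exp(y))), tolerance = 1e-10)
})

test_that("a symmetric two-token model predicts 50/50", {
    ## one sentence alternating two tokens; epochs = 0 keeps the zero
    ## softmax parameters, so both branches of the single tree node are
    ## equally likely
    seqs <- c(DOC_1 = strrep("AC", 30))
    corp <- kmerCorpus(seqs, k = 1, s = 1)
    model <- trainEmbedding(corp, trainConfig(k = 1, d = 4, m = 2,
                                              epochs = 0, seed = 1))
    p <- nextWordProbability(model, c("A", "C"), "DOC_1")
    expect_equal(unname(p), c(0.5, 0.5))
})

test_that("training improves the objective over the initialization", {
    seqs <- randomSeqSet(10, 80, seed = 5)
    corp <- kmerCorpus(seqs, k = 3, s = 1)
    for (mode in c("hierarchical", "exact")) {
        cfg0 <- trainConfig(k = 3, d = 8, m = 3, epochs = 0, mode = mode,
                            seed = 5)
        cfgE <- trainConfig(k = 3, d = 8, m = 3, epochs = 5, mode = mode,
                            seed = 5)
        lp0 <- corpusLogProb(trainEmbedding(corp, cfg0), corp)
        lpE <- corpusLogProb(trainEmbedding(corp, cfgE), corp)
        expect_gt(lpE, lp0)
    }
})

test_that("objective improvement holds across seeds", {
    for (seed in 1:5) {
        seqs <- randomSeqSet(8, 70, seed = 100 + seed)
        corp <- kmerCorpus(seqs, k = 3, s = 1)
        lp0 <- corpusLogProb(trainEmbedding(corp,
            trainConfig(k = 3, d = 8, m = 3, epochs = 0, seed = seed)), corp)
        lpE <- corpusLogProb(trainEmbedding(corp,
            trainConfig(k = 3, d = 8, m = 3, epochs = 4, seed = seed)), corp)
        expect_gt(lpE, lp0)
    }
})

test_that("identical sentences converge to similar document vectors", {
    withr::with_seed(8, {
        base <- randomDNA(120)
        seqs <- c(TWIN_1 = base, TWIN_2 = base,
                  setNames(vapply(1:10, function(i) randomDNA(120), ""),
                           paste0("OTHER_", 1:10)))
    })
    corp <- kmerCorpus(seqs, k = 3, s = 1)
    model <- trainEmbedding(corp, trainConfig(k = 3, d = 12, m = 3,
                                              epochs = 30, seed = 3))
    D <- docVectors(model)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    C <- crossprod(D)
    twin <- C["TWIN_1", "TWIN_2"]
    others <- C[paste0("OTHER_", 1:10), paste0("OTHER_", 1:10)]
    null <- others[upper.tri(others)]
    expect_gt(twin, quantile(null, 0.95))
})

test_that("training is bit-reproducible for a fixed seed", {
    seqs <- randomSeqSet(6, 60, seed = 12)
    corp <- kmerCorpus(seqs, k = 3, s = 1)
    cfg <- trainConfig(k = 3, d = 8, m = 3, epochs = 3, seed = 99)
    m1 <- trainEmbedding(corp, cfg)
    m2 <- trainEmbedding(corp, cfg)
    expect_identical(docVectors(m1), docVectors(m2))
    expect_identical(wordVectors(m1), wordVectors(m2))
    ## and a different seed gives different vectors
    m3 <- trainEmbedding(corp, trainConfig(k = 3, d = 8, m = 3,
                                           epochs = 3, seed = 100))
    expect_false(identical(docVectors(m1), docVectors(m3)))
})

test_that("document vectors are retrieved by id with clear errors", {
    fx <- tinyModel()
    v <- docVector(fx$model, "ENHANCER_4")
    expect_length(v, 8L)
    expect_true(all(is.finite(v)) && sum(v^2) > 0)
    expect_identical(v, docVector(fx$model, "ENHANCER_4"))
    expect_error(docVector(fx$model, "UNSEEN"), "inferVector")
})

test_that("sentences no longer than m are skipped or rejected", {
    seqs <- c(LONG_1 = randomDNA(60), LONG_2 = randomDNA(60),
              SHORT = randomDNA(5))
    corp <- kmerCorpus(seqs, k = 3, s = 1)
    expect_warning(
        model <- trainEmbedding(corp, trainConfig(k = 3, d = 4, m = 3,
                                                  epochs = 1)),
        "skipped")
    short <- kmerCorpus(c(A = randomDNA(5), B = randomDNA(5)), k = 3)
    expect_error(
        trainEmbedding(short, trainConfig(k = 3, d = 4, m = 10, epochs = 1)),
        "lower m")
})

test_that("inferVector reproduces training-document geometry", {
    fx <- tinyModel(n = 12, len = 100, epochs = 10)
    sent <- fx$corpus@sentences[["ENHANCER_1"]]
    v <- inferVector(fx$model, sent, seed = 7)
    expect_length(v, 8L)
    D <- docVectors(fx$model)
    sims <- as.vector(crossprod(D, v)) /
        (sqrt(colSums(D^2)) * sqrt(sum(v^2)))
    names(sims) <- colnames(D)
    expect_gt(sims[["ENHANCER_1"]], median(sims))
    ## reproducible under the same seed; random init returned at 0 steps
    expect_identical(v, inferVector(fx$model, sent, seed = 7))
    v0a <- inferVector(fx$model, sent, epochs = 0, seed = 3)
    v0b <- inferVector(fx$model, sent, epochs = 0, seed = 3)
    expect_identical(v0a, v0b)
    expect_error(inferVector(fx$model, sent[1:2]), "T > m")
})

test_that("model serialization round-trips losslessly", {
    fx <- tinyModel()
    path <- tempfile(fileext = ".model")
    writeEmbeddingModel(fx$model, path)
    back <- readEmbeddingModel(path)
    for (sl in slotNames(class(fx$model)))
        expect_identical(slot(back, sl), slot(fx$model, sl), info = sl)
    ## wrong payloads are rejected
    saveRDS(list(format = "something-else"), path)
    expect_error(readEmbeddingModel(path), "not an epivec model")
})

test_that("embedding separates documents by planted motif content", {
    ## half the documents share an 8-bp planted motif; their vectors
    ## should be mutually closer than motif/no-motif pairs (sign test
    ## across seeds)
    wins <- 0L
    for (seed in 1:5) {
        withr::with_seed(200 + seed, {
            motif <- "TGACTCAG"
            seqs <- character(30)
            for (i in 1:30) {
                s <- randomDNA(200)
                if (i <= 15)
                    for (r in 1:6) {
                        at <- sample(1:(200 - 8), 1)
                        substr(s, at, at + 7) <- motif
                    }
                seqs[i] <- s
            }
            names(seqs) <- paste0("DOC_", 1:30)
        })
        corp <- kmerCorpus(seqs, k = 4, s = 1)
        model <- trainEmbedding(corp, trainConfig(k = 4, d = 16, m = 5,
                                                  epochs = 5, seed = seed))
        cc <- classCosine(model, rep(c("motif", "none"), each = 15))
        if (cc[["within"]] > cc[["between"]]) wins <- wins + 1L
    }
    expect_gte(wins, 4L)
})
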
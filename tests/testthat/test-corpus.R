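test_that("tokenize reproduces the worked 6-mer example", {
    s <- tokenize("ATGCAACAC", k = 6, s = 1, docId = "SEQUENCE_1")
    expect_identical(s@kmers, c("ATGCAA", "TGCAAC", "GCAACA", "CAACAC"))
    expect_length(s@tokens, 4L)
})

test_that("tokenize boundary cases follow the count formula", {
    ## L = k gives exactly one token: the sequence itself
    s <- tokenize("ACGTAC", k = 6, s = 1)
    expect_identical(s@kmers, "ACGTAC")
    ## L < k gives an empty sentence with a warning, not an error
    expect_warning(s0 <- tokenize("ACG", k = 6, s = 1), "shorter than k")
    expect_length(s0@tokens, 0L)
    ## lowercase input is uppercased before windowing
    expect_identical(tokenize("acgtac", k = 3, s = 3)@kmers, c("ACG", "TAC"))
})

test_that("token count matches brute-force window enumeration", {
    withr::with_seed(11, {
        for (i in 1:200) {
            L <- sample(1:300, 1)
            k <- sample(1:12, 1)
            s <- sample(1:5, 1)
            seq <- randomDNA(L)
            got <- length(suppressWarnings(tokenize(seq, k = k, s = s))@kmers)
            expect_identical(got, oracleTokenCount(L, k, s),
                info = sprintf("L=%d k=%d s=%d", L, k, s))
        }
    })
    ## the worked stride example: 200 bp, k = 6, s = 3 -> 65 tokens
    expect_length(tokenize(randomDNA(200), k = 6, s = 3)@kmers,
                  oracleTokenCount(200, 6, 3))
    expect_identical(oracleTokenCount(200, 6, 3), 65L)
})

test_that("s = 1 tokenization is order-preserving and invertible", {
    withr::with_seed(3, {
        for (i in 1:20) {
            seq <- randomDNA(sample(10:60, 1))
            km <- tokenize(seq, k = 4, s = 1)@kmers
            rebuilt <- paste0(km[1],
                paste(substring(km[-1], 4, 4), collapse = ""))
            expect_identical(rebuilt, seq)
        }
    })
})

test_that("non-ACGT windows become UNK but keep their position", {
    s <- tokenize("ACGTNACGTA", k = 4, s = 1)
    expect_length(s@kmers, oracleTokenCount(10L, 4L, 1L))
    expect_identical(which(s@kmers == "UNK"), 2:5)
    vocab <- buildVocabulary(list(s))
    expect_false("UNK" %in% tokens(vocab))
    expect_identical(vocab@unkCount, 4L)
    ## with a vocabulary, UNK windows encode as index 0
    enc <- tokenize("ACGTNACGTA", k = 4, s = 1, vocab = vocab)
    expect_identical(enc@tokens[2:5], rep(0L, 4))
})

test_that("FASTA round trip preserves ids and sequences", {
    seqs <- randomSeqSet(5, 40, seed = 9)
    path <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    back <- loadFasta(path, role = "enhancer")
    expect_identical(names(back), names(seqs))
    expect_identical(unname(as.character(back)), unname(seqs))
    expect_identical(unique(S4Vectors::mcols(back)$role), "enhancer")
})

test_that("FASTA headers are trimmed at whitespace; errors are raised", {
    path <- writeTestFasta(c(">ENHANCER_0 extra text", "ACGTACGT",
                             ">ENHANCER_1", "acgtacgt"))
    x <- loadFasta(path)
    expect_identical(names(x), c("ENHANCER_0", "ENHANCER_1"))
    expect_identical(as.character(x)[[2]], "ACGTACGT")  # uppercased

    dup <- writeTestFasta(c(">A", "ACGT", ">A", "TTTT"))
    expect_error(loadFasta(dup), "duplicate")

    bad <- writeTestFasta(c("ACGT", ">A", "ACGT"))
    expect_error(loadFasta(bad), "line 1")
})

test_that("BED extraction is 0-based half-open with strand handling", {
    genome <- c(chr1 = "ACGTACGTGGTTACCAGTAC", chr2 = randomDNA(50))
    gpath <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), gpath)

    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t0\t6\tE1\t0\t+",
                 "chr1\t4\t12\tE2\t0\t-",
                 "chr2\t10\t20\tE3\t0\t+"), bed)
    x <- extractFromGenome(gpath, bed, role = "enhancer")
    expect_identical(names(x), c("E1", "E2", "E3"))
    expect_identical(as.character(x)[["E1"]], substr(genome[["chr1"]], 1, 6))
    expect_identical(as.character(x)[["E2"]], as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(
            substr(genome[["chr1"]], 5, 12)))))
    expect_identical(as.character(x)[["E3"]], substr(genome[["chr2"]], 11, 20))
    expect_identical(unname(nchar(as.character(x))), c(6L, 8L, 10L))
})

test_that("BED extraction validates chromosomes and bounds", {
    genome <- c(chr1 = randomDNA(100))
    gpath <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), gpath)

    bed1 <- tempfile(); writeLines("chrX\t0\t10", bed1)
    expect_error(extractFromGenome(gpath, bed1), "unknown chromosome")

    bed2 <- tempfile(); writeLines("chr1\t90\t120", bed2)
    expect_error(extractFromGenome(gpath, bed2), "out of chromosome bounds")

    ## nameless intervals get synthesized role ids
    bed3 <- tempfile(); writeLines(c("chr1\t0\t10", "chr1\t20\t30"), bed3)
    x <- extractFromGenome(gpath, bed3, role = "promoter")
    expect_identical(names(x), c("PROMOTER_1", "PROMOTER_2"))
})

test_that("pair tables load, validate ids and keep distances", {
    enh <- randomSeqSet(3, 30, role = "ENHANCER", seed = 1)
    prom <- randomSeqSet(3, 30, role = "PROMOTER", seed = 2)
    path <- tempfile(fileext = ".tsv")
    writeLines(c("enh_id\tprom_id\tlabel\tdistance",
                 "ENHANCER_1\tPROMOTER_1\t1\t50000",
                 "ENHANCER_2\tPROMOTER_2\t1\t90000",
                 "ENHANCER_3\tPROMOTER_1\t0\t40000",
                 "ENHANCER_1\tPROMOTER_3\t0\t150000"), path)
    expect_message(ds <- loadPairs(path, enh, prom), "2 positive")
    expect_s4_class(ds, "PairDataset")
    expect_identical(nrow(pairTable(ds)), 4L)
    expect_identical(pairTable(ds)$distance,
                     c(50000L, 90000L, 40000L, 150000L))

    bad <- tempfile()
    writeLines(c("enh_id\tprom_id\tlabel",
                 "ENHANCER_1\tPROMOTER_9\t1"), bad)
    expect_error(loadPairs(bad, enh, prom), "PROMOTER_9")

    nb <- tempfile()
    writeLines(c("enh_id\tprom_id\tlabel",
                 "ENHANCER_1\tPROMOTER_1\t2"), nb)
    expect_error(loadPairs(nb, enh, prom), "binary")
})

test_that("kmerCorpus builds a consistent shared vocabulary", {
    seqs <- randomSeqSet(6, 50, seed = 4)
    corp <- kmerCorpus(seqs, k = 3, s = 1)
    vocab <- vocabulary(corp)
    expect_lte(vocabSize(vocab), 64L)
    ## counts re-derived by brute force from the raw sequences
    all <- unlist(lapply(seqs, function(x)
        tokenize(x, k = 3, s = 1)@kmers))
    expect_identical(sum(tokenCounts(vocab)), length(all))
    expect_identical(sort(tokens(vocab)), sort(unique(all)))
    ## every encoded token index is valid
    expect_true(all(unlist(corp@sentences) %in% 0:vocabSize(vocab)))
    ## duplicate ids are rejected
    dup <- setNames(randomSeqSet(2, 30), c("A", "A"))
    expect_error(kmerCorpus(dup, k = 3), "duplicate")
})

test_that("external feature tables attach and validate", {
    enh <- randomSeqSet(2, 30, role = "ENHANCER")
    prom <- randomSeqSet(2, 30, role = "PROMOTER")
    path <- tempfile()
    writeLines(c("enh_id\tprom_id\tlabel",
                 "ENHANCER_1\tPROMOTER_1\t1",
                 "ENHANCER_2\tPROMOTER_2\t0"), path)
    ds <- suppressMessages(loadPairs(path, enh, prom))
    ext <- matrix(1:4 / 2, nrow = 2)
    ds2 <- attachExternalFeatures(ds, ext)
    expect_identical(dim(externalFeatures(ds2)), c(2L, 2L))
    expect_error(attachExternalFeatures(ds, matrix(1, 3, 2)), "match")
})
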
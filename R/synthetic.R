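## synthetic_data: ground-truth benchmark corpora with planted PWM
## motifs, motif-compatibility-defined positive pairs and
## distance-binned negative sampling.

#' Build a sharp position-weight matrix from a consensus
#'
#' Each column gives probability \code{strength} to the consensus base
#' and (1 - strength)/3 to the other three.
#'
#' @param consensus character string over ACGT.
#' @param strength numeric in (1/4, 1], per-position consensus
#'   probability.
#' @return A 4 x nchar(consensus) probability matrix with rows
#'   A, C, G, T.
#' @export
consensusPWM <- function(consensus, strength = 0.85) {
    bases <- c("A", "C", "G", "T")
    cons <- strsplit(toupper(consensus), "")[[1L]]
    stopifnot(all(cons %in% bases), strength > 0.25, strength <= 1)
    pwm <- matrix((1 - strength) / 3, nrow = 4L, ncol = length(cons),
                  dimnames = list(bases, NULL))
    for (j in seq_along(cons)) pwm[cons[j], j] <- strength
    pwm
}

#' Specification of a synthetic enhancer-promoter benchmark
#'
#' Defines the study conditions of the built-in benchmark: corpus
#' sizes, per-role uniform sequence-length ranges, the planted PWM
#' motif set with per-role class probabilities and copy counts, the
#' pairing rule (interaction probability per enhancer-class x
#' promoter-class combination), background base composition, and the
#' distance model (elements placed on one synthetic chromosome, pair
#' distances restricted to at least 10 kb, negatives subsampled within
#' five distance bins, one per positive).
#'
#' The default pairing rule is a single compatible motif combination:
#' sequences of the "act" class carry the active motif, "dec" sequences
#' a decoy; a pair interacts with probability 0.9 when both members are
#' "act" and 0.03 otherwise, so labels carry realistic noise.
#'
#' @param nEnhancers,nPromoters integer corpus sizes.
#' @param enhancerLength,promoterLength integer length-2 bp ranges.
#' @param motifStrength numeric consensus probability of the planted
#'   PWMs.
#' @param enhancerMotifs,promoterMotifs named lists of 4 x width PWMs.
#' @param enhancerClassProbs,promoterClassProbs named class
#'   probabilities (must match the motif lists).
#' @param copyRange integer length-2, planted copies per sequence.
#' @param interactionProb matrix of interaction probabilities,
#'   enhancer classes x promoter classes.
#' @param baseComposition numeric length-4 background probabilities
#'   (A, C, G, T).
#' @param nCandidatePairs integer candidate pairs drawn before
#'   labelling.
#' @param minDistance,maxDistance,chromLength numeric bp.
#' @param nBins integer distance bins for negative matching.
#' @param negativesPerPositive integer.
#' @param seed integer default seed.
#' @return A [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nEnhancers = 50, nPromoters = 50, nCandidatePairs = 100)
#' @export
syntheticSpec <- function(nEnhancers = 400L, nPromoters = 400L,
                          enhancerLength = c(400L, 1200L),
                          promoterLength = c(800L, 1800L),
                          motifStrength = 0.75,
                          enhancerMotifs = list(
                              act = consensusPWM("TGACTCAGCA", motifStrength),
                              dec = consensusPWM("CACGTGTTAC", motifStrength)),
                          promoterMotifs = list(
                              act = consensusPWM("GGGGCGGAAC", motifStrength),
                              dec = consensusPWM("CCAATCAGTG", motifStrength)),
                          enhancerClassProbs = c(act = 0.5, dec = 0.5),
                          promoterClassProbs = c(act = 0.5, dec = 0.5),
                          copyRange = c(16L, 24L),
                          interactionProb = rbind(act = c(act = 0.9, dec = 0.03),
                                                  dec = c(act = 0.03, dec = 0.03)),
                          baseComposition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                          nCandidatePairs = 800L,
                          minDistance = 1e4, maxDistance = 2e6,
                          chromLength = 5e7, nBins = 5L,
                          negativesPerPositive = 1L, seed = 1L) {
    new("SyntheticSpec",
        nEnhancers = as.integer(nEnhancers),
        nPromoters = as.integer(nPromoters),
        enhancerLength = as.integer(enhancerLength),
        promoterLength = as.integer(promoterLength),
        enhancerMotifs = enhancerMotifs, promoterMotifs = promoterMotifs,
        enhancerClassProbs = enhancerClassProbs,
        promoterClassProbs = promoterClassProbs,
        copyRange = as.integer(copyRange),
        interactionProb = interactionProb,
        baseComposition = baseComposition,
        nCandidatePairs = as.integer(nCandidatePairs),
        minDistance = minDistance, maxDistance = maxDistance,
        chromLength = chromLength, nBins = as.integer(nBins),
        negativesPerPositive = as.integer(negativesPerPositive),
        seed = as.integer(seed))
}

sampleMotif <- function(pwm) {
    bases <- rownames(pwm)
    paste(vapply(seq_len(ncol(pwm)), function(j)
        sample(bases, 1L, prob = pwm[, j]), character(1)), collapse = "")
}

#' Generate synthetic sequences with planted motifs
#'
#' Draws i.i.d. background DNA from the spec's base composition, picks
#' a motif class per sequence, and plants PWM-sampled motif copies at
#' uniform random non-overlapping positions.  Lengths are uniform in
#' the role's range; genomic coordinates are uniform on the synthetic
#' chromosome.  Fully deterministic for a given seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param role "enhancer" or "promoter".
#' @param seed integer seed (default: the spec's).
#' @return A list with \code{sequences} (a named
#'   [Biostrings::DNAStringSet] with metadata columns \code{role},
#'   \code{class}, \code{pos}) and \code{truth} (data.frame of planted
#'   motif positions: \code{doc_id}, \code{class}, \code{motif},
#'   \code{start}, \code{end}).
#' @export
generateSequences <- function(spec, role = c("enhancer", "promoter"),
                              seed = NULL) {
    role <- match.arg(role)
    seed <- seed %||% spec@seed
    n <- if (role == "enhancer") spec@nEnhancers else spec@nPromoters
    lenR <- if (role == "enhancer") spec@enhancerLength else spec@promoterLength
    motifs <- if (role == "enhancer") spec@enhancerMotifs else spec@promoterMotifs
    classP <- if (role == "enhancer") spec@enhancerClassProbs
              else spec@promoterClassProbs
    wmax <- max(vapply(motifs, ncol, integer(1)))
    if (wmax > lenR[1L])
        stop("motif width ", wmax, " exceeds the minimum ", role,
             " length ", lenR[1L], call. = FALSE)
    bases <- c("A", "C", "G", "T")
    ids <- paste0(toupper(role), "_", seq_len(n))
    withSeed(seed, {
        lens <- sample(lenR[1L]:lenR[2L], n, replace = TRUE)
        classes <- sample(names(classP), n, replace = TRUE, prob = classP)
        coords <- sort(sample.int(as.integer(spec@chromLength), n))
        plants <- vector("list", n)
        seqs <- character(n)
        for (i in seq_len(n)) {
            s <- sample(bases, lens[i], replace = TRUE,
                        prob = spec@baseComposition)
            pwm <- motifs[[classes[i]]]
            w <- ncol(pwm)
            nCopies <- if (spec@copyRange[2L] == 0L) 0L
                       else sample(spec@copyRange[1L]:spec@copyRange[2L], 1L)
            starts <- integer(0)
            tries <- 0L
            while (length(starts) < nCopies && tries < 200L) {
                cand <- sample.int(lens[i] - w + 1L, 1L)
                if (!any(abs(cand - starts) < w)) starts <- c(starts, cand)
                tries <- tries + 1L
            }
            for (st in starts) {
                inst <- strsplit(sampleMotif(pwm), "")[[1L]]
                s[st:(st + w - 1L)] <- inst
            }
            seqs[i] <- paste(s, collapse = "")
            plants[[i]] <- if (length(starts))
                data.frame(doc_id = ids[i], class = classes[i],
                           motif = classes[i], start = sort(starts),
                           end = sort(starts) + w - 1L,
                           stringsAsFactors = FALSE)
            else NULL
        }
        dna <- Biostrings::DNAStringSet(seqs)
        names(dna) <- ids
        S4Vectors::mcols(dna) <- S4Vectors::DataFrame(
            role = role, class = classes, pos = coords)
        truth <- do.call(rbind, plants)
        if (is.null(truth))
            truth <- data.frame(doc_id = character(0), class = character(0),
                                motif = character(0), start = integer(0),
                                end = integer(0))
        list(sequences = dna, truth = truth)
    })
}

#' Generate labelled pairs with distance-matched negatives
#'
#' Draws candidate enhancer-promoter pairs whose genomic distances lie
#' in the spec's range, labels each by the pairing rule (interaction
#' probability of its class combination), keeps the positives, and
#' subsamples negatives within distance bins so that the negative
#' distance distribution matches the positive one: the positives are
#' split into \code{nBins} equal-count bins and
#' \code{negativesPerPositive} negatives are drawn per positive from
#' the same bin.
#'
#' @param spec a [SyntheticSpec-class].
#' @param enhancers,promoters outputs of [generateSequences()]
#'   (the \code{sequences} element).
#' @param seed integer seed (default: the spec's).
#' @return A [PairDataset-class] whose pair table carries the
#'   generative rationale columns \code{enh_class}, \code{prom_class}
#'   and \code{bin} in addition to ids, label and distance.
#' @export
generatePairs <- function(spec, enhancers, promoters, seed = NULL) {
    seed <- seed %||% spec@seed
    mE <- S4Vectors::mcols(enhancers)
    mP <- S4Vectors::mcols(promoters)
    withSeed(seed, {
        nDraw <- 60L * spec@nCandidatePairs
        ei <- sample.int(length(enhancers), nDraw, replace = TRUE)
        pj <- sample.int(length(promoters), nDraw, replace = TRUE)
        dist <- abs(mE$pos[ei] - mP$pos[pj])
        ok <- dist >= spec@minDistance & dist <= spec@maxDistance &
            !duplicated(paste(ei, pj))
        ei <- ei[ok]; pj <- pj[ok]; dist <- dist[ok]
        if (length(ei) < spec@nCandidatePairs)
            stop("only ", length(ei), " candidate pairs in the distance ",
                 "range; enlarge the corpus or the chromosome",
                 call. = FALSE)
        keep <- seq_len(spec@nCandidatePairs)
        ei <- ei[keep]; pj <- pj[keep]; dist <- dist[keep]
        pInt <- spec@interactionProb[cbind(mE$class[ei], mP$class[pj])]
        label <- rbinom(length(ei), 1L, pInt)
        if (sum(label) == 0L)
            stop("pairing rule produced zero positives; ",
                 "raise the interaction probabilities", call. = FALSE)

        posD <- dist[label == 1L]
        edges <- unique(quantile(posD, probs = seq(0, 1, length.out =
                                                       spec@nBins + 1L)))
        bin <- cut(dist, breaks = edges, include.lowest = TRUE,
                   labels = FALSE)
        posIdx <- which(label == 1L)
        negIdx <- integer(0)
        for (bn in seq_len(length(edges) - 1L)) {
            needed <- spec@negativesPerPositive *
                sum(bin[posIdx] == bn, na.rm = TRUE)
            avail <- which(label == 0L & !is.na(bin) & bin == bn)
            if (length(avail) < needed)
                stop("distance bin ", bn, " has ", length(avail),
                     " candidate negatives but needs ", needed,
                     "; enlarge nCandidatePairs or the corpus",
                     call. = FALSE)
            negIdx <- c(negIdx, sample(avail, needed))
        }
        sel <- sample(c(posIdx, negIdx))   # shuffle row order
        df <- data.frame(
            enh_id = names(enhancers)[ei[sel]],
            prom_id = names(promoters)[pj[sel]],
            label = label[sel],
            distance = as.integer(dist[sel]),
            enh_class = mE$class[ei[sel]],
            prom_class = mP$class[pj[sel]],
            bin = bin[sel],
            stringsAsFactors = FALSE)
        new("PairDataset", pairs = df,
            external = matrix(numeric(0), 0L, 0L))
    })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: generates both corpora and the labelled pairs
#' from one spec and one seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed integer seed (default: the spec's).
#' @return A list with \code{enhancers}, \code{promoters} (named
#'   DNAStringSets with metadata), \code{truth} (list with
#'   \code{enhancer} and \code{promoter} plant tables) and
#'   \code{pairs} (a [PairDataset-class]).
#' @export
simulateDataset <- function(spec = syntheticSpec(), seed = NULL) {
    seed <- seed %||% spec@seed
    enh <- generateSequences(spec, "enhancer", seed = childSeed(seed, 1L))
    prom <- generateSequences(spec, "promoter", seed = childSeed(seed, 2L))
    pairs <- generatePairs(spec, enh$sequences, prom$sequences,
                           seed = childSeed(seed, 3L))
    list(enhancers = enh$sequences, promoters = prom$sequences,
         truth = list(enhancer = enh$truth, promoter = prom$truth),
         pairs = pairs)
}

#' Write a synthetic benchmark to disk
#'
#' Writes \code{enhancers.fa}, \code{promoters.fa}, \code{pairs.tsv}
#' (columns enh_id, prom_id, label, distance) and
#' \code{ground_truth.tsv} (planted motif positions), in the formats
#' consumed by [loadFasta()] and [loadPairs()].
#'
#' @param dataset a [PairDataset-class].
#' @param enhancers,promoters named [Biostrings::DNAStringSet]s.
#' @param truth list with \code{enhancer}/\code{promoter} plant tables
#'   (may be NULL to skip the ground-truth file).
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(dataset, enhancers, promoters, truth = NULL,
                         dir = ".") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(enhancers = file.path(dir, "enhancers.fa"),
               promoters = file.path(dir, "promoters.fa"),
               pairs = file.path(dir, "pairs.tsv"),
               truth = file.path(dir, "ground_truth.tsv"))
    Biostrings::writeXStringSet(enhancers, paths[["enhancers"]])
    Biostrings::writeXStringSet(promoters, paths[["promoters"]])
    df <- pairTable(dataset)
    keep <- intersect(c("enh_id", "prom_id", "label", "distance"), names(df))
    write.table(df[, keep], paths[["pairs"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(truth)) {
        tr <- rbind(
            cbind(role = "enhancer", truth$enhancer),
            cbind(role = "promoter", truth$promoter))
        write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else paths <- paths[1:3]
    invisible(paths)
}
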
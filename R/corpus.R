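## sequence_corpus: reading sequences and pair tables, and rendering
## DNA sequences as k-mer sentences.

#' Tokenize a DNA sequence into a k-mer sentence
#'
#' Splits a sequence of length L into its ordered k-mer words using a
#' sliding window with stride \code{s}, yielding
#' \eqn{T = \lfloor (L-k)/s \rfloor + 1} tokens for \eqn{L \ge k}
#' (trailing bases that do not complete a window are dropped).  Windows
#' containing any non-ACGT character become the reserved UNK token:
#' they keep their position in the sentence (so T is unchanged) but are
#' excluded from prediction targets during training.  A sequence
#' shorter than k yields an empty sentence (T = 0) with a warning.
#'
#' @param record a single sequence: a character string, a
#'   [Biostrings::DNAString] or a length-1 named
#'   [Biostrings::DNAStringSet].
#' @param k integer word length in bp (>= 1).
#' @param s integer stride in bp between adjacent windows (>= 1).
#' @param vocab optional [KmerVocabulary-class]; when supplied, tokens
#'   are encoded as indices into it (k-mers absent from the vocabulary
#'   map to UNK), otherwise indices are left unset and only the k-mer
#'   strings are stored.
#' @param docId document id; defaults to the name of \code{record}.
#' @return A [KmerSentence-class].
#' @examples
#' tokenize("ATGCAACAC", k = 6, s = 1, docId = "SEQUENCE_1")
#' @export
tokenize <- function(record, k = 6L, s = 1L, vocab = NULL, docId = NULL) {
    stopifnot(k >= 1L, s >= 1L)
    k <- as.integer(k); s <- as.integer(s)
    if (is(record, "DNAStringSet")) {
        stopifnot(length(record) == 1L)
        docId <- docId %||% names(record)
        record <- as.character(record[[1L]])
    } else if (is(record, "DNAString")) {
        record <- as.character(record)
    }
    stopifnot(is.character(record), length(record) == 1L)
    docId <- docId %||% names(record) %||% NA_character_
    seq <- toupper(record)
    L <- nchar(seq)
    if (L < k) {
        warning("sequence ", docId, " shorter than k (", L, " < ", k,
                "); empty sentence (T = 0)", call. = FALSE)
        return(new("KmerSentence", docId = as.character(docId),
                   tokens = integer(0), kmers = character(0), k = k, s = s))
    }
    starts <- seq.int(1L, L - k + 1L, by = s)
    kmers <- substring(seq, starts, starts + k - 1L)
    unk <- grepl("[^ACGT]", kmers)
    kmers[unk] <- "UNK"
    idx <- if (is.null(vocab)) rep(NA_integer_, length(kmers)) else {
        i <- match(kmers, vocab@tokens)
        i[is.na(i)] <- 0L       # UNK and out-of-vocabulary windows
        i
    }
    new("KmerSentence", docId = as.character(docId), tokens = idx,
        kmers = kmers, k = k, s = s)
}

#' Build a k-mer vocabulary from tokenized sentences
#'
#' Collects every distinct observed k-mer across the corpus into a
#' dense, lexicographically ordered index \code{1..V} with corpus
#' frequencies.  The vocabulary can hold at most \eqn{4^k} tokens; the
#' reserved UNK token is counted separately and never indexed.
#'
#' @param sentences a list of [KmerSentence-class] objects, or a list
#'   of character vectors of k-mer strings.
#' @param k integer word length (required when \code{sentences} are
#'   bare character vectors).
#' @return A [KmerVocabulary-class].
#' @examples
#' buildVocabulary(list(c("ATGCAA", "TGCAAC", "GCAACA", "CAACAC")), k = 6)
#' @export
buildVocabulary <- function(sentences, k = NULL) {
    if (length(sentences) == 0L)
        stop("empty corpus: no sentences", call. = FALSE)
    if (is(sentences[[1L]], "KmerSentence")) {
        k <- sentences[[1L]]@k
        words <- unlist(lapply(sentences, function(x) x@kmers),
                        use.names = FALSE)
    } else {
        stopifnot(!is.null(k))
        words <- unlist(sentences, use.names = FALSE)
    }
    if (length(words) == 0L)
        stop("empty corpus: no tokens in any sentence", call. = FALSE)
    unkCount <- sum(words == "UNK")
    words <- words[words != "UNK"]
    tab <- table(words)
    new("KmerVocabulary", tokens = names(tab),
        counts = as.integer(tab), k = as.integer(k),
        unkCount = as.integer(unkCount))
}

#' Tokenize a set of sequences into a corpus with a shared vocabulary
#'
#' Convenience constructor for the training unit: tokenizes every
#' sequence, builds the vocabulary over the whole set and encodes all
#' sentences against it.  Enhancers and promoters are embedded
#' separately, so they should be placed in separate corpora.
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character
#'   vector of DNA sequences.
#' @param k,s integers, word length and stride in bp.
#' @param role role of the sequences ("enhancer" or "promoter"),
#'   recycled; taken from \code{mcols(seqs)$role} when present.
#' @return A [KmerCorpus-class].
#' @examples
#' seqs <- c(ENHANCER_1 = "ATGCAACACGTT", ENHANCER_2 = "GGGCAACACGTA")
#' kmerCorpus(seqs, k = 6, s = 1, role = "enhancer")
#' @export
kmerCorpus <- function(seqs, k = 6L, s = 1L, role = "enhancer") {
    if (is(seqs, "DNAStringSet")) {
        if (!is.null(S4Vectors::mcols(seqs)$role))
            role <- S4Vectors::mcols(seqs)$role
        ids <- names(seqs)
        chr <- as.character(seqs)
    } else {
        ids <- names(seqs)
        chr <- toupper(as.character(seqs))
    }
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        stop("all sequences must be named with a document id", call. = FALSE)
    if (anyDuplicated(ids))
        stop("duplicate document ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    role <- rep_len(as.character(role), length(ids))
    sents <- lapply(seq_along(chr), function(i)
        tokenize(chr[[i]], k = k, s = s, docId = ids[[i]]))
    vocab <- buildVocabulary(sents)
    enc <- lapply(sents, function(x) {
        i <- match(x@kmers, vocab@tokens)
        i[is.na(i)] <- 0L
        i
    })
    names(enc) <- ids
    new("KmerCorpus", sentences = enc, docIds = ids, roles = role,
        vocabulary = vocab, k = as.integer(k), s = as.integer(s))
}

#' Read sequences from a FASTA file
#'
#' Reads one record per FASTA entry; ids are the header text up to the
#' first whitespace and sequences are normalized to uppercase.
#' Duplicate ids are an error.
#'
#' @param path path to a FASTA file.
#' @param role role to attach to every record ("enhancer" or
#'   "promoter").
#' @return A named [Biostrings::DNAStringSet] with a \code{role}
#'   metadata column.
#' @seealso [Biostrings::readDNAStringSet()], which performs the
#'   parsing.
#' @export
loadFasta <- function(path, role = c("enhancer", "promoter")) {
    role <- match.arg(role)
    if (!file.exists(path))
        stop("FASTA file not found: ", path, call. = FALSE)
    first <- readLines(path, n = 50L)
    nonblank <- which(nzchar(trimws(first)))
    if (length(nonblank) == 0L || !startsWith(first[nonblank[1L]], ">"))
        stop("malformed FASTA at line ", if (length(nonblank)) nonblank[1L] else 1L,
             ": expected a '>' header", call. = FALSE)
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
             call. = FALSE)
    S4Vectors::mcols(x)$role <- role
    x
}

#' Extract enhancer or promoter sequences from a genome by BED intervals
#'
#' Treats the BED file as 0-based half-open intervals (the BED
#' standard); record ids come from the BED name column when present,
#' otherwise \code{"<ROLE>_<i>"}.  A strand column, when present,
#' triggers reverse-complementation of minus-strand intervals.
#' Soft-masked (lowercase) genome bases are uppercased, not masked.
#'
#' @param genomeFasta path to the genome FASTA.
#' @param bedPath path to a 3-6 column BED file.
#' @param role "enhancer" or "promoter".
#' @return A named [Biostrings::DNAStringSet] with a \code{role}
#'   metadata column.
#' @export
extractFromGenome <- function(genomeFasta, bedPath,
                              role = c("enhancer", "promoter")) {
    role <- match.arg(role)
    genome <- Biostrings::readDNAStringSet(genomeFasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    gr <- rtracklayer::import(bedPath, format = "BED")
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chr), names(genome))
    if (length(unknown))
        stop("unknown chromosome(s) in BED: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    chrLen <- setNames(Biostrings::width(genome), names(genome))
    st <- GenomicRanges::start(gr)   # rtracklayer converts BED to 1-based
    en <- GenomicRanges::end(gr)
    bad <- st < 1L | en > chrLen[chr]
    if (any(bad))
        stop("BED interval(s) out of chromosome bounds: ",
             paste(sprintf("%s:%d-%d", chr[bad], st[bad] - 1L, en[bad]),
                   collapse = ", "), call. = FALSE)
    seqs <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(i)
        Biostrings::subseq(genome[[chr[i]]], st[i], en[i])))
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    if (any(minus))
        seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    ids <- gr$name
    if (is.null(ids)) ids <- rep(NA_character_, length(gr))
    auto <- is.na(ids) | ids == ""
    ids[auto] <- paste0(toupper(role), "_", which(auto))
    names(seqs) <- ids
    S4Vectors::mcols(seqs)$role <- role
    seqs
}

#' Load a labelled enhancer-promoter pair table
#'
#' Reads a tab-separated table with header columns \code{enh_id},
#' \code{prom_id}, \code{label} and optionally \code{distance} (bp).
#' Every id must resolve to a sequence of the correct role and labels
#' must be binary.
#'
#' @param path path to the TSV file.
#' @param enhancers,promoters named [Biostrings::DNAStringSet] objects
#'   (or any named objects / character vectors of ids) the pair ids
#'   must resolve against.
#' @return A [PairDataset-class].
#' @export
loadPairs <- function(path, enhancers, promoters) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("enh_id", "prom_id", "label")
    if (!all(need %in% names(df)))
        stop("pair table must have header columns ",
             paste(need, collapse = ", "), call. = FALSE)
    idsOf <- function(x) if (is.character(x) && is.null(names(x))) x else names(x)
    badE <- setdiff(df$enh_id, idsOf(enhancers))
    if (length(badE))
        stop("unresolvable enhancer id(s): ",
             paste(head(badE, 5L), collapse = ", "), call. = FALSE)
    badP <- setdiff(df$prom_id, idsOf(promoters))
    if (length(badP))
        stop("unresolvable promoter id(s): ",
             paste(head(badP, 5L), collapse = ", "), call. = FALSE)
    if (!all(df$label %in% c(0L, 1L)))
        stop("labels must be binary 0/1", call. = FALSE)
    df$label <- as.integer(df$label)
    message("loaded ", nrow(df), " pairs: ", sum(df$label == 1L),
            " positive, ", sum(df$label == 0L), " negative")
    keep <- intersect(c("enh_id", "prom_id", "label", "distance"), names(df))
    new("PairDataset", pairs = df[, keep, drop = FALSE],
        external = matrix(numeric(0), 0L, 0L))
}

#' Attach external per-pair experimental features
#'
#' Attaches a per-pair numeric feature table for the combined-features
#' classifier mode, in which the 2d sequence embedding features are
#' concatenated with experimental features.
#'
#' @param dataset a [PairDataset-class].
#' @param features a numeric matrix/data.frame with one row per pair,
#'   or a path to a tab-separated numeric table (header required).
#' @return The dataset with external features attached.
#' @export
attachExternalFeatures <- function(dataset, features) {
    stopifnot(is(dataset, "PairDataset"))
    if (is.character(features))
        features <- read.delim(features, header = TRUE, sep = "\t")
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != nrow(dataset@pairs))
        stop("external feature rows (", nrow(features),
             ") must match pair count (", nrow(dataset@pairs), ")",
             call. = FALSE)
    if (anyNA(features))
        stop("external features must not contain missing values",
             call. = FALSE)
    dataset@external <- features
    validObject(dataset)
    dataset
}
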
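#' @rdname accessors
#' @export
setMethod("wordCount", "Wordbook", function(x) nrow(x@words))

#' @rdname accessors
#' @export
setMethod("wordMatrix", "Wordbook", function(x) x@words)

#' @rdname accessors
#' @export
setMethod("shapeOffsets", "Wordbook", function(x) x@shape@offsets)

setMethod("show", "Wordbook", function(object) {
    cat("Wordbook ", object@id, ": ", nrow(object@words), " words, offsets (",
        paste(object@shape@offsets, collapse = ","), ")\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("featureDim", "WordbookSet",
    function(x) sum(vapply(x@books, wordCount, integer(1))))

setMethod("show", "WordbookSet", function(object) {
    ks <- vapply(object@books, wordCount, integer(1))
    cat("WordbookSet (", object@scaleName, " scale, seed ", object@seed, ")\n",
        "  words: ", paste(names(ks), ks, sep = "=", collapse = ", "),
        "  -> feature dimension ", sum(ks), "\n", sep = "")
})

seqsAsCharacter <- function(sequences) {
    if (is(sequences, "XStringSet")) {
        out <- as.character(sequences)
        names(out) <- names(sequences)
        sequences <- out
    }
    if (!is.character(sequences) || length(sequences) < 1L)
        stop("'sequences' must be a non-empty named character vector ",
             "or an AAStringSet")
    if (is.null(names(sequences)))
        names(sequences) <- paste0("seq", seq_along(sequences))
    sequences
}

#' Learn the four wordbooks from a set of sequences
#'
#' Encodes every sequence with the hydropathy scale, pools the fragments
#' of each learned shape (B: contiguous pairs, C: contiguous triples,
#' D: gapped pairs) across all sequences, and clusters each pool with
#' seeded K-means; the cluster centers become the words.  Wordbook A is
#' fixed to the 20 amino acids (amino-acid composition) and is never
#' clustered.  The number of words per learned book is either fixed
#' through `K` or chosen by [selectK()] when `K = "auto"`.
#'
#' @param sequences named character vector of amino-acid strings, or an
#'   `AAStringSet`
#' @param K either a named integer vector `c(B=,C=,D=)` (default
#'   `c(B=16, C=62, D=16)`) or `"auto"` for WSC-based selection
#' @param kCandidates candidate K values used when `K = "auto"`
#' @param scale hydropathy scale, default [kyteDoolittleScale()]
#' @param seed integer seed; identical seeds give identical wordbooks
#' @param subsample fragment cap for [selectK()]
#' @param nstart K-means restarts
#' @param selfInclusive passed to [wsc()] during selection
#' @return a [WordbookSet]
#' @examples
#' seqs <- c(p1 = "MKTIIALSYIFCLVFA", p2 = "GGIVEQCCTSICSLYQLENYCN")
#' wb <- buildWordbooks(seqs, K = c(B = 3, C = 3, D = 3), seed = 1)
#' featureDim(wb)
#' @export
buildWordbooks <- function(sequences, K = c(B = 16L, C = 62L, D = 16L),
                           kCandidates = 2:100,
                           scale = kyteDoolittleScale(), seed = 1L,
                           subsample = 2000L, nstart = 10L,
                           selfInclusive = TRUE) {
    sequences <- seqsAsCharacter(sequences)
    checkScale(scale)
    shapes <- wordbookShapes()
    enc <- lapply(sequences, encodeSequence, scale = scale)
    auto <- identical(K, "auto")
    if (!auto) {
        K <- as.integer(K[c("B", "C", "D")])
        if (any(is.na(K)) || any(K < 1L))
            stop("'K' must give positive counts for B, C and D, or be \"auto\"")
        names(K) <- c("B", "C", "D")
    }
    aaOrder <- sort(names(scale))
    wbA <- new("Wordbook", id = "A", shape = shapes$A,
               words = matrix(unname(scale[aaOrder]), ncol = 1L,
                              dimnames = list(aaOrder, NULL)))
    books <- list(A = wbA)
    for (id in c("B", "C", "D")) {
        pooled <- do.call(rbind, lapply(enc, extractFragments,
                                        shape = shapes[[id]]))
        if (is.null(pooled) || nrow(pooled) == 0L)
            stop("no fragments available for wordbook ", id,
                 ": sequences are too short")
        k <- if (auto) {
            selectK(pooled, kCandidates = kCandidates, seed = seed,
                    subsample = subsample, nstart = nstart,
                    selfInclusive = selfInclusive)$bestK
        } else K[[id]]
        k <- min(k, nrow(unique(pooled)))  # degenerate-input cap
        set.seed(seed + match(id, c("B", "C", "D")))
        km <- seededKmeans(pooled, k, nstart = nstart)
        words <- unique(km$centers)  # coincident centers collapse to one word
        books[[id]] <- new("Wordbook", id = id, shape = shapes[[id]],
                           words = words)
    }
    new("WordbookSet", books = books, scale = scale,
        scaleName = "Kyte-Doolittle hydropathy", seed = as.integer(seed))
}

nearestWord <- function(frags, words) {
    # squared Euclidean; ties resolved toward the lowest word index
    cross <- frags %*% t(words)
    d2 <- outer(rowSums(frags^2), rowSums(words^2), "+") - 2 * cross
    max.col(-d2, ties.method = "first")
}

#' Bag-of-words feature vector of one sequence
#'
#' Block A is the amino-acid composition over standard residues; blocks
#' B, C and D assign every fragment of the matching shape to its nearest
#' word (Euclidean distance, ties toward the lowest word index) and
#' report the relative frequency of each word.  Blocks are concatenated
#' in order A, B, C, D; a block whose shape yields no fragments is all
#' zeros, otherwise it sums to 1.
#'
#' @param seq single amino-acid string
#' @param wordbooks a [WordbookSet] from [buildWordbooks()]
#' @return numeric vector of length [featureDim()] of the wordbook set,
#'   named `f_A_1 .. f_D_K`
#' @export
featurizeGPCR <- function(seq, wordbooks) {
    stopifnot(is(wordbooks, "WordbookSet"))
    scale <- wordbooks@scale
    enc <- encodeSequence(seq, scale)
    aaOrder <- rownames(wordbooks@books$A@words)
    letters1 <- strsplit(seq, "", fixed = TRUE)[[1L]]
    std <- letters1[letters1 %in% aaOrder]
    if (length(std) == 0L)
        stop("sequence contains no standard amino-acid residues")
    blockA <- as.numeric(table(factor(std, levels = aaOrder))) / length(std)
    blocks <- list(A = blockA)
    for (id in c("B", "C", "D")) {
        wb <- wordbooks@books[[id]]
        frags <- extractFragments(enc, wb@shape)
        k <- wordCount(wb)
        if (nrow(frags) == 0L) {
            blocks[[id]] <- numeric(k)
        } else {
            hit <- nearestWord(frags, wb@words)
            blocks[[id]] <- as.numeric(tabulate(hit, nbins = k)) / nrow(frags)
        }
    }
    v <- unlist(blocks, use.names = FALSE)
    names(v) <- unlist(lapply(names(blocks), function(id)
        paste0("f_", id, "_", seq_len(length(blocks[[id]])))))
    v
}

#' Featurize many sequences against one wordbook set
#'
#' @param sequences named character vector or `AAStringSet`
#' @param wordbooks a [WordbookSet]
#' @return numeric matrix, one row per sequence (rownames = ids)
#' @export
featurizeSequences <- function(sequences, wordbooks) {
    sequences <- seqsAsCharacter(sequences)
    m <- t(vapply(sequences, featurizeGPCR, numeric(featureDim(wordbooks)),
                  wordbooks = wordbooks))
    rownames(m) <- names(sequences)
    m
}

#' Write / read a wordbook archive
#'
#' Wordbook sets are persisted as structured JSON (shapes, K values, word
#' matrices, scale, seed) so featurization is reproducible at full double
#' precision.
#'
#' @param wordbooks a [WordbookSet]
#' @param path file path for the JSON archive
#' @return `writeWordbooks()` returns `path` invisibly;
#'   `readWordbooks()` returns the reconstructed [WordbookSet]
#' @export
writeWordbooks <- function(wordbooks, path) {
    stopifnot(is(wordbooks, "WordbookSet"))
    obj <- list(
        scaleName = wordbooks@scaleName,
        scale = as.list(wordbooks@scale),
        seed = wordbooks@seed,
        books = lapply(wordbooks@books, function(b) list(
            id = b@id,
            offsets = b@shape@offsets,
            letters = if (b@id == "A") rownames(b@words) else NULL,
            words = apply(b@words, 1L, as.numeric, simplify = FALSE))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeWordbooks
#' @export
readWordbooks <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    scale <- unlist(obj$scale)
    books <- lapply(obj$books, function(b) {
        words <- do.call(rbind, lapply(b$words, unlist))
        if (!is.null(b$letters)) rownames(words) <- unlist(b$letters)
        new("Wordbook", id = b$id,
            shape = fragmentShape(unlist(b$offsets)), words = words)
    })
    names(books) <- vapply(books, function(b) b@id, character(1))
    new("WordbookSet", books = books[c("A", "B", "C", "D")], scale = scale,
        scaleName = obj$scaleName, seed = as.integer(obj$seed))
}
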
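#' Kyte-Doolittle hydropathy scale
#'
#' The canonical hydropathy index (AAindex KYTJ820101): one dimensionless
#' value per standard amino acid, positive for hydrophobic residues.
#' This is the per-residue encoding used throughout the bag-of-words
#' featurizer; alternative 20-letter scales can be passed wherever a
#' `scale` argument is accepted.
#'
#' @return named numeric vector of length 20 (names are one-letter codes)
#' @examples
#' kyteDoolittleScale()[c("A", "C", "D", "E")]
#' @export
kyteDoolittleScale <- function() {
    c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

checkScale <- function(scale) {
    if (!is.numeric(scale) || length(scale) != 20L ||
        is.null(names(scale)) || anyDuplicated(names(scale)) ||
        !all(nchar(names(scale)) == 1L))
        stop("'scale' must be a named numeric vector over the 20 standard ",
             "amino-acid one-letter codes")
    invisible(scale)
}

#' Encode an amino-acid sequence as a hydropathy signal
#'
#' Each residue is replaced by its scale value.  Non-standard letters
#' (B, J, O, U, X, Z, and anything else outside the scale) are masked
#' with `NA` rather than rejected; downstream fragment extraction drops
#' any window touching a masked position.
#'
#' @param seq single amino-acid string, upper case
#' @param scale named numeric scale, default [kyteDoolittleScale()]
#' @return numeric vector, one value per residue, `NA` at masked positions
#' @examples
#' encodeSequence("ACDE")
#' encodeSequence("AXA")   # position 2 masked
#' @export
encodeSequence <- function(seq, scale = kyteDoolittleScale()) {
    checkScale(scale)
    if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
        stop("'seq' must be a single non-empty string")
    letters1 <- strsplit(seq, "", fixed = TRUE)[[1L]]
    unname(scale[letters1])
}

#' Construct a fragment shape
#'
#' @param offsets integer residue offsets from the window start; strictly
#'   increasing and starting at 0
#' @return a [FragmentShape]
#' @examples
#' fragmentShape(c(0, 2))  # gapped pair, residues separated by one
#' @export
fragmentShape <- function(offsets) {
    new("FragmentShape", offsets = as.integer(offsets), stride = 1L)
}

#' The four wordbook fragment shapes
#'
#' Single residue (A), contiguous pair (B), contiguous triple (C) and the
#' pair separated by one residue (D).
#'
#' @return named list of [FragmentShape]s
#' @export
wordbookShapes <- function() {
    list(A = fragmentShape(0L),
         B = fragmentShape(0:1),
         C = fragmentShape(0:2),
         D = fragmentShape(c(0L, 2L)))
}

#' @rdname accessors
#' @export
setMethod("shapeOffsets", "FragmentShape", function(x) x@offsets)

setMethod("show", "FragmentShape", function(object) {
    cat("FragmentShape: offsets (", paste(object@offsets, collapse = ","),
        "), stride ", object@stride, "\n", sep = "")
})

#' Extract sequence fragments for one shape
#'
#' Slides a window of span `max(offsets) + 1` along the encoded sequence
#' with stride 1 and samples the encoded values at the shape's offsets.
#' Windows touching a masked (`NA`) residue are dropped.  A sequence
#' shorter than the window span yields a 0-row matrix.
#'
#' @param enc numeric vector from [encodeSequence()]
#' @param shape a [FragmentShape]
#' @return numeric matrix with one row per fragment and
#'   `length(offsets)` columns; attribute `"start"` holds the 1-based
#'   window start position of each retained fragment
#' @export
extractFragments <- function(enc, shape) {
    stopifnot(is(shape, "FragmentShape"), is.numeric(enc))
    off <- shape@offsets
    span <- max(off) + 1L
    L <- length(enc)
    n <- L - span + 1L
    if (n < 1L) {
        m <- matrix(numeric(0), nrow = 0L, ncol = length(off))
        attr(m, "start") <- integer(0)
        return(m)
    }
    starts <- seq_len(n)
    m <- vapply(off, function(o) enc[starts + o], numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    keep <- !apply(is.na(m), 1L, any)
    m <- m[keep, , drop = FALSE]
    attr(m, "start") <- starts[keep]
    m
}
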
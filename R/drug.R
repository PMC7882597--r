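#' Parse a hexadecimal fingerprint into an integer signal
#'
#' An FP2-style fingerprint is a 256-character hexadecimal string; each
#' character is read as one signal sample with value 0-15, preserving
#' string order.
#'
#' @param hex single string of exactly 256 hexadecimal characters
#' @return integer vector of length 256, values in 0-15
#' @examples
#' sig <- parseFingerprint(strrep("0a", 128))
#' sig[1:4]
#' @export
parseFingerprint <- function(hex) {
    if (!is.character(hex) || length(hex) != 1L || is.na(hex))
        stop("'hex' must be a single string")
    if (nchar(hex) != 256L)
        stop("fingerprint must have exactly 256 hexadecimal characters, got ",
             nchar(hex))
    vals <- match(strsplit(tolower(hex), "", fixed = TRUE)[[1L]],
                  c(0:9, letters[1:6])) - 1L
    if (anyNA(vals))
        stop("non-hexadecimal character at position ", which(is.na(vals))[1L])
    vals
}

checkSignal <- function(sig) {
    if (!is.numeric(sig) || length(sig) != 256L || anyNA(sig))
        stop("'sig' must be a numeric signal of length 256")
    invisible(sig)
}

#' Drug features by discrete Fourier transform
#'
#' Amplitudes (moduli) of the first 128 DFT bins of the length-256
#' fingerprint signal, starting at the DC bin.  For a real signal the
#' spectrum is conjugate-symmetric, so the first half carries all the
#' amplitude information.
#'
#' @param sig numeric signal of length 256 (from [parseFingerprint()])
#' @return numeric vector `F_1 .. F_128` of nonnegative amplitudes
#' @export
dftFeatures <- function(sig) {
    checkSignal(sig)
    v <- Mod(stats::fft(sig))[1:128]
    names(v) <- paste0("F_", 1:128)
    v
}

#' Drug features by single-level Haar wavelet transform
#'
#' Single-level Haar decomposition of the fingerprint signal: the 128
#' approximation coefficients `a_i = (x_[2i-1] + x_[2i]) / sqrt(2)` are
#' kept as the feature vector; the detail coefficients are treated as
#' noise and discarded.  The length-256 signal needs no boundary padding.
#'
#' @inheritParams dftFeatures
#' @return numeric vector `W_1 .. W_128` of approximation coefficients
#' @export
dwtFeatures <- function(sig) {
    checkSignal(sig)
    odd <- sig[seq(1L, 255L, by = 2L)]
    even <- sig[seq(2L, 256L, by = 2L)]
    v <- (odd + even) / sqrt(2)
    names(v) <- paste0("W_", 1:128)
    v
}

haarDetail <- function(sig) {
    # internal: detail coefficients, used to verify energy conservation
    checkSignal(sig)
    (sig[seq(1L, 255L, by = 2L)] - sig[seq(2L, 256L, by = 2L)]) / sqrt(2)
}

#' Feature matrix for a set of fingerprints
#'
#' @param fingerprints named character vector of 256-character hex strings
#'   (names are drug ids)
#' @param mode `"dwt"` (default) or `"dft"`
#' @return numeric matrix, one row per drug, 128 columns
#' @export
drugFeatureMatrix <- function(fingerprints, mode = c("dwt", "dft")) {
    mode <- match.arg(mode)
    if (is.null(names(fingerprints)))
        stop("'fingerprints' must be named by drug id")
    f <- if (mode == "dwt") dwtFeatures else dftFeatures
    m <- t(vapply(fingerprints, function(h) f(parseFingerprint(h)),
                  numeric(128)))
    rownames(m) <- names(fingerprints)
    m
}
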
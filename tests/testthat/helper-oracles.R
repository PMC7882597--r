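# Independent brute-force oracles used to validate the vectorized
# implementations.  These deliberately follow the defining formulas
# step by step and share no code with the package internals.

# weighted distance, written out directly
oracleWdist <- function(d) (1 / (1 + exp(-d))) * d

# per-sample weighted silhouette by explicit double loops
oracleWSCSamples <- function(x, labels, selfInclusive = TRUE) {
    x <- as.matrix(x)
    M <- nrow(x)
    sapply(seq_len(M), function(i) {
        own <- which(labels == labels[i])
        if (length(own) == 1L) return(0)
        dOwn <- sapply(own, function(j) oracleWdist(sqrt(sum((x[i, ] - x[j, ])^2))))
        din <- if (selfInclusive) mean(dOwn) else sum(dOwn) / (length(own) - 1L)
        dex <- min(sapply(setdiff(unique(labels), labels[i]), function(cl) {
            mem <- which(labels == cl)
            mean(sapply(mem, function(j)
                oracleWdist(sqrt(sum((x[i, ] - x[j, ])^2)))))
        }))
        if (max(dex, din) == 0) 0 else (dex - din) / max(dex, din)
    })
}

# O(n^2) discrete Fourier transform amplitudes
oracleDFTAmplitudes <- function(sig, nBins = 128L) {
    n <- length(sig)
    sapply(seq_len(nBins) - 1L, function(k) {
        re <- sum(sig * cos(-2 * pi * k * (seq_len(n) - 1L) / n))
        im <- sum(sig * sin(-2 * pi * k * (seq_len(n) - 1L) / n))
        sqrt(re^2 + im^2)
    })
}

# AUC as the exhaustive pairwise-comparison probability
oracleAUC <- function(y, s) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# random fingerprint hex strings
randomHex <- function(n, seed = 1) {
    set.seed(seed)
    replicate(n, paste(sample(c(0:9, letters[1:6]), 256, replace = TRUE),
                       collapse = ""))
}

# random sequences over the 20 standard residues
randomSeqs <- function(n, len = 80, seed = 1) {
    set.seed(seed)
    out <- replicate(n, paste(sample(names(kyteDoolittleScale()), len,
                                     replace = TRUE), collapse = ""))
    names(out) <- paste0("P", seq_len(n))
    out
}

# a desk-scale benchmark for fast pipeline tests
tinyConfig <- function(seed = 7) {
    synthConfig(nGpcrs = 18, lengthRange = c(60, 120), nDrugs = 12,
                nPairs = 90, seed = seed)
}

tinyPipelineConfig <- function(seed = 7, ...) {
    pipelineConfig(wordbookK = c(B = 4, C = 6, D = 4), annEpochs = 20,
                   classifierParams = list(nrounds = 30), seed = seed, ...)
}
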
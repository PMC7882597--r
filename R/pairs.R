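#' @rdname accessors
#' @export
setMethod("featureMatrix", "PairFeatures", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("pairLabels", "PairFeatures", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("featureDim", "PairFeatures", function(x) ncol(x@features))

setMethod("show", "PairFeatures", function(object) {
    cat("PairFeatures: ", nrow(object@features), " pairs x ",
        ncol(object@features), " features (",
        sum(object@label == 1L), " interactive / ",
        sum(object@label == 0L), " non-interactive",
        if (any(object@synthetic)) paste0("; ", sum(object@synthetic),
                                          " synthetic") else "",
        ")\n", sep = "")
})

setMethod("dim", "PairFeatures", function(x) dim(x@features))

#' Assemble GPCR-drug pair feature vectors
#'
#' Each pair's row is the GPCR bag-of-words vector followed by the
#' 128-coefficient drug block, giving `dim(G) + 128` columns (242 with
#' the default word counts 20/16/62/16).  Duplicated pairs are kept as
#' duplicated rows.
#'
#' @param gpcrFeatures matrix from [featurizeSequences()] (rownames = ids)
#' @param drugFeatures matrix from [drugFeatureMatrix()] (rownames = ids)
#' @param pairs data.frame with columns `gpcr_id`, `drug_id`, `label`
#' @return a [PairFeatures] object
#' @export
assemblePairs <- function(gpcrFeatures, drugFeatures, pairs) {
    need <- c("gpcr_id", "drug_id", "label")
    if (!all(need %in% names(pairs)))
        stop("'pairs' must have columns gpcr_id, drug_id, label")
    gi <- match(as.character(pairs$gpcr_id), rownames(gpcrFeatures))
    di <- match(as.character(pairs$drug_id), rownames(drugFeatures))
    missing <- c(unique(pairs$gpcr_id[is.na(gi)]),
                 unique(pairs$drug_id[is.na(di)]))
    if (length(missing))
        stop("ids not found in the feature stores: ",
             paste(missing, collapse = ", "))
    lab <- as.integer(pairs$label)
    if (nrow(pairs) > 0L && !all(lab %in% c(0L, 1L)))
        stop("labels must be 0 or 1")
    x <- cbind(gpcrFeatures[gi, , drop = FALSE],
               drugFeatures[di, , drop = FALSE])
    rownames(x) <- NULL
    new("PairFeatures", features = x,
        gpcrId = as.character(pairs$gpcr_id),
        drugId = as.character(pairs$drug_id),
        label = lab, synthetic = rep(FALSE, nrow(pairs)))
}

#' SMOTE oversampling of the minority class (matrix interface)
#'
#' For each minority sample, its `k` nearest minority neighbors
#' (Euclidean) are found and synthetic samples are drawn on the segment
#' between the sample and a randomly chosen neighbor:
#' `x_new = x_i + alpha * (x_ij - x_i)` with `alpha ~ Uniform(0, 1)`.
#' Enough samples are synthesized to balance the classes exactly: the
#' per-sample synthesis counts differ by at most one, with the remainder
#' assigned to the first minority samples in index order.  With
#' `paperLiteral = TRUE` the interpolation sign is flipped to
#' `x_new = x_i + alpha * (x_i - x_ij)`, which extrapolates away from
#' the neighbor.
#'
#' @param x numeric feature matrix
#' @param y binary labels (0/1), one per row; both classes present
#' @param k neighbor count (default 5); must be below the minority size
#' @param seed integer seed
#' @param paperLiteral flip the interpolation sign (default `FALSE`)
#' @return list with `x` (original rows first, then synthetic), `y`, and
#'   logical `synthetic` flags
#' @export
smoteMatrix <- function(x, y, k = 5L, seed = 1L, paperLiteral = FALSE) {
    x <- as.matrix(x)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("SMOTE needs both classes present")
    counts <- table(factor(y, levels = sort(unique(y))))
    minLab <- as.integer(names(counts)[which.min(counts)])
    minIdx <- which(y == minLab)
    m <- length(minIdx)
    need <- max(counts) - m
    if (need == 0L)
        return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
    if (m <= k)
        stop("minority class size (", m, ") must exceed k (", k, ")")
    xm <- x[minIdx, , drop = FALSE]
    D <- as.matrix(stats::dist(xm))
    diag(D) <- Inf
    nn <- t(apply(D, 1L, function(r) order(r)[seq_len(k)]))
    nPer <- rep(need %/% m, m)
    rem <- need %% m
    if (rem > 0L) nPer[seq_len(rem)] <- nPer[seq_len(rem)] + 1L
    set.seed(seed)
    synth <- vector("list", m)
    for (i in seq_len(m)) {
        if (nPer[i] == 0L) next
        nbr <- nn[i, sample.int(k, nPer[i], replace = TRUE), drop = TRUE]
        alpha <- stats::runif(nPer[i])
        xi <- matrix(xm[i, ], nPer[i], ncol(x), byrow = TRUE)
        xj <- xm[nbr, , drop = FALSE]
        synth[[i]] <- if (paperLiteral) xi + alpha * (xi - xj)
                      else xi + alpha * (xj - xi)
    }
    xs <- do.call(rbind, synth)
    list(x = rbind(x, xs),
         y = c(y, rep(minLab, nrow(xs))),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(xs))))
}

#' @describeIn smoteOversample matrix method; see [smoteMatrix()]
#' @param y,k,seed,paperLiteral see [smoteMatrix()]
#' @export
setMethod("smoteOversample", "matrix",
    function(x, y, k = 5L, seed = 1L, paperLiteral = FALSE)
        smoteMatrix(x, y, k = k, seed = seed, paperLiteral = paperLiteral))

#' @describeIn smoteOversample balance a [PairFeatures] object; synthetic
#'   rows get ids `"smote"` and are flagged in the `synthetic` slot
#' @export
setMethod("smoteOversample", "PairFeatures",
    function(x, k = 5L, seed = 1L, paperLiteral = FALSE) {
        out <- smoteMatrix(x@features, x@label, k = k, seed = seed,
                           paperLiteral = paperLiteral)
        nS <- sum(out$synthetic)
        new("PairFeatures", features = out$x,
            gpcrId = c(x@gpcrId, rep("smote", nS)),
            drugId = c(x@drugId, rep("smote", nS)),
            label = as.integer(out$y),
            synthetic = out$synthetic)
    })
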
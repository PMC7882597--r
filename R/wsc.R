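#' Logistic-weighted distance
#'
#' Damps a Euclidean distance by a logistic weight:
#' `wdist(d) = d / (1 + exp(-d))`.  The weight approaches 1 for large
#' distances, so `wdist` shrinks small distances relative to large ones
#' while preserving their order.
#'
#' @param d nonnegative numeric vector of distances
#' @return numeric vector, `0 <= wdist(d) < d` for `d > 0`
#' @examples
#' weightedDistance(c(0, 1, 20))
#' @export
weightedDistance <- function(d) {
    if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
        stop("'d' must be nonnegative and finite")
    d / (1 + exp(-d))
}

wscCore <- function(x, labels, selfInclusive = TRUE) {
    x <- as.matrix(x)
    labels <- as.integer(factor(labels))
    M <- nrow(x)
    if (length(labels) != M) stop("one label per sample required")
    C <- max(labels)
    if (C < 2L)
        stop("at least two clusters are required to evaluate the ",
             "weighted silhouette coefficient")
    W <- as.matrix(stats::dist(x))
    W <- W / (1 + exp(-W))
    ind <- outer(labels, seq_len(C), "==")  # M x C membership
    sizes <- colSums(ind)
    S <- W %*% ind                           # row sums of W per cluster
    own <- cbind(seq_len(M), labels)
    if (selfInclusive) {
        din <- S[own] / sizes[labels]
    } else {
        # W[i,i] = 0 so the numerator is unchanged; singleton handled below
        din <- S[own] / pmax(sizes[labels] - 1, 1)
    }
    meanS <- sweep(S, 2L, sizes, "/")
    meanS[own] <- Inf
    dex <- apply(meanS, 1L, min)
    denom <- pmax(dex, din)
    s <- ifelse(denom > 0, (dex - din) / denom, 0)
    s[sizes[labels] == 1L] <- 0              # singleton-cluster convention
    unname(s)
}

#' Per-sample weighted silhouette coefficients
#'
#' For each sample the internal mean weighted distance (to the members of
#' its own cluster, self included by default) is compared with the
#' smallest external mean weighted distance (over the other clusters):
#' `(dex - din) / max(dex, din)`.  A sample in a singleton cluster, or
#' one for which both means vanish, scores 0 by convention.
#'
#' @param x numeric sample matrix (rows = samples)
#' @param labels cluster labels, one per row, at least two distinct
#' @param selfInclusive logical; if `TRUE` (default) the internal mean
#'   averages over all own-cluster members including the sample itself
#'   (whose self-distance is 0); if `FALSE`, the classical variant that
#'   excludes the sample
#' @return numeric vector in \[-1, 1\], one value per sample
#' @export
wscSamples <- function(x, labels, selfInclusive = TRUE) {
    wscCore(x, labels, selfInclusive)
}

#' Weighted silhouette coefficient of a clustering
#'
#' The mean of [wscSamples()] over all samples; used as the
#' model-selection statistic for the number of wordbook words.
#'
#' @inheritParams wscSamples
#' @return a single number in \[-1, 1\]
#' @export
wsc <- function(x, labels, selfInclusive = TRUE) {
    mean(wscCore(x, labels, selfInclusive))
}

## --- seeded k-means with k-means++ initialization ---------------------

kmeansPPCenters <- function(x, k) {
    n <- nrow(x)
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1L) for (j in 2:k) {
        idx[j] <- if (all(d2 <= 0)) sample.int(n, 1L)
                  else sample.int(n, 1L, prob = d2)
        dj <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
        d2 <- pmin(d2, dj)
    }
    x[idx, , drop = FALSE]
}

#' Seeded K-means with k-means++ restarts
#'
#' Lloyd's algorithm (via [stats::kmeans()]) started from k-means++
#' seedings; the best of `nstart` restarts (lowest total within-cluster
#' sum of squares) is kept.  `k` is capped at the number of distinct
#' rows; if the distinct rows are no more than `k` they become the
#' centers directly.
#'
#' @param x numeric sample matrix
#' @param k requested number of clusters
#' @param nstart number of k-means++ restarts (default 10)
#' @param iterMax Lloyd iteration cap per restart
#' @return list with `centers` (matrix), `cluster` (integer labels) and
#'   `k` (the effective cluster count after capping)
#' @export
seededKmeans <- function(x, k, nstart = 10L, iterMax = 100L) {
    x <- as.matrix(x)
    ux <- unique(x)
    if (nrow(ux) <= k) {
        key <- apply(x, 1L, paste, collapse = "\r")
        ukey <- apply(ux, 1L, paste, collapse = "\r")
        return(list(centers = ux, cluster = match(key, ukey), k = nrow(ux)))
    }
    best <- NULL
    for (s in seq_len(nstart)) {
        init <- kmeansPPCenters(x, k)
        km <- tryCatch(
            suppressWarnings(stats::kmeans(x, centers = init,
                                           iter.max = iterMax,
                                           algorithm = "Lloyd")),
            error = function(e) NULL)
        if (is.null(km))  # rare empty-cluster failure: MacQueen fallback
            km <- tryCatch(
                suppressWarnings(stats::kmeans(x, centers = init,
                                               iter.max = iterMax,
                                               algorithm = "MacQueen")),
                error = function(e) NULL)
        if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
            best <- km
    }
    if (is.null(best)) stop("k-means failed for all restarts")
    list(centers = unname(best$centers), cluster = unname(best$cluster),
         k = nrow(best$centers))
}

#' Select the number of words by the weighted silhouette coefficient
#'
#' Runs seeded K-means for every candidate K and scores the clustering
#' with [wsc()]; returns the K with the highest score (ties broken toward
#' the smallest K) together with the whole profile.  Because the
#' silhouette cost is quadratic in the number of fragments, the fragment
#' set is subsampled (seeded, uniform) to at most `subsample` rows before
#' profiling.
#'
#' @param frags numeric fragment matrix (rows = fragments)
#' @param kCandidates integer candidates, all `>= 2`
#' @param seed integer seed controlling subsampling and K-means
#' @param subsample maximum number of fragments used (default 2000)
#' @param nstart K-means restarts per candidate
#' @param selfInclusive passed to [wsc()]
#' @return list with `bestK` and `profile` (data.frame of `K`, `WSC`)
#' @export
selectK <- function(frags, kCandidates = 2:100, seed = 1L,
                    subsample = 2000L, nstart = 10L, selfInclusive = TRUE) {
    frags <- as.matrix(frags)
    kCandidates <- sort(unique(as.integer(kCandidates)))
    if (any(kCandidates < 2L)) stop("all K candidates must be >= 2")
    if (nrow(frags) <= max(kCandidates))
        stop("too few fragments (", nrow(frags), ") for the largest ",
             "candidate K (", max(kCandidates), ")")
    set.seed(seed)
    if (nrow(frags) > subsample)
        frags <- frags[sample.int(nrow(frags), subsample), , drop = FALSE]
    prof <- vapply(kCandidates, function(k) {
        set.seed(seed + k)
        km <- seededKmeans(frags, k, nstart = nstart)
        if (km$k < 2L) return(NA_real_)
        wsc(frags, km$cluster, selfInclusive = selfInclusive)
    }, numeric(1))
    ok <- !is.na(prof)
    if (!any(ok)) stop("no candidate K produced a valid clustering")
    bestK <- kCandidates[ok][which.max(prof[ok])]
    list(bestK = bestK, profile = data.frame(K = kCandidates, WSC = prof))
}
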
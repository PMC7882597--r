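#' Configuration of the feed-forward feature compressor
#'
#' A small fully connected network: the first hidden layer has as many
#' units as the input, and every further hidden layer halves the width
#' (`floor(w / 2)`); the output layer is a single sigmoid unit trained on
#' the interaction label.  Hidden activations are LeakyReLU.  After
#' training, the activations of the `tapLayer`-th hidden layer are used
#' as the compressed features (layer 2 by default: 242 -> 121 with the
#' standard pair dimension).
#'
#' @param inputDim input width (242 with default word counts)
#' @param hiddenLayers number of hidden layers (2 or 3)
#' @param tapLayer hidden layer to tap for features (default 2)
#' @param learningRate SGD learning rate (default 0.01)
#' @param epochs training epochs (default 100)
#' @param batchSize minibatch size (default 128)
#' @param leakySlope LeakyReLU negative slope (default 0.3)
#' @param seed integer seed for initialization and batching
#' @return list of class-less configuration values, with `widths` the
#'   hidden-layer widths by the halving rule
#' @export
annConfig <- function(inputDim = 242L, hiddenLayers = 2L, tapLayer = 2L,
                      learningRate = 0.01, epochs = 100L, batchSize = 128L,
                      leakySlope = 0.3, seed = 1L) {
    stopifnot(hiddenLayers >= 1L, tapLayer >= 1L, tapLayer <= hiddenLayers)
    widths <- integer(hiddenLayers)
    widths[1L] <- as.integer(inputDim)
    if (hiddenLayers > 1L)
        for (i in 2:hiddenLayers) widths[i] <- widths[i - 1L] %/% 2L
    list(inputDim = as.integer(inputDim), hiddenLayers = as.integer(hiddenLayers),
         widths = widths, tapLayer = as.integer(tapLayer),
         learningRate = learningRate, epochs = as.integer(epochs),
         batchSize = as.integer(batchSize), leakySlope = leakySlope,
         seed = as.integer(seed))
}

glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

lrelu <- function(z, s) ifelse(z > 0, z, s * z)
lreluGrad <- function(z, s) ifelse(z > 0, 1, s)

annForward <- function(weights, x, slope) {
    nH <- length(weights) - 1L
    acts <- vector("list", nH)
    a <- x
    for (i in seq_len(nH)) {
        z <- sweep(a %*% weights[[i]]$W, 2L, weights[[i]]$b, "+")
        a <- lrelu(z, slope)
        acts[[i]] <- list(z = z, a = a)
    }
    zo <- sweep(a %*% weights[[nH + 1L]]$W, 2L, weights[[nH + 1L]]$b, "+")
    p <- 1 / (1 + exp(-zo))
    list(acts = acts, p = p)
}

#' Train the feed-forward feature compressor
#'
#' Supervised training with minibatch stochastic gradient descent on the
#' binary cross-entropy loss; deterministic given the configuration seed.
#' With `epochs = 0` the returned extractor is the (seeded) Glorot
#' initialization.
#'
#' @param x numeric feature matrix, `ncol(x)` must equal the configured
#'   input width
#' @param y binary labels (0/1)
#' @param config from [annConfig()]
#' @return an [AnnExtractor]
#' @export
trainANN <- function(x, y, config = annConfig(inputDim = ncol(x))) {
    x <- as.matrix(x)
    y <- as.numeric(y)
    if (ncol(x) != config$inputDim)
        stop("input has ", ncol(x), " columns but the network expects ",
             config$inputDim)
    if (length(y) != nrow(x)) stop("one label per row required")
    set.seed(config$seed)
    dims <- c(config$inputDim, config$widths, 1L)
    weights <- lapply(seq_len(length(dims) - 1L), function(i)
        list(W = glorot(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L])))
    nH <- config$hiddenLayers
    lr <- config$learningRate
    slope <- config$leakySlope
    n <- nrow(x)
    lossHist <- numeric(config$epochs)
    if (config$epochs > 0L) for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = config$batchSize)
        epLoss <- 0
        for (s in starts) {
            idx <- ord[s:min(s + config$batchSize - 1L, n)]
            xb <- x[idx, , drop = FALSE]
            yb <- y[idx]
            fwd <- annForward(weights, xb, slope)
            p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
            epLoss <- epLoss - sum(yb * log(p) + (1 - yb) * log(1 - p))
            m <- length(idx)
            delta <- (fwd$p - yb) / m          # d(loss)/d(z_out)
            for (i in rev(seq_len(nH + 1L))) {
                aPrev <- if (i == 1L) xb else fwd$acts[[i - 1L]]$a
                gW <- crossprod(aPrev, delta)
                gb <- colSums(delta)
                if (i > 1L) {
                    delta <- (delta %*% t(weights[[i]]$W)) *
                        lreluGrad(fwd$acts[[i - 1L]]$z, slope)
                }
                weights[[i]]$W <- weights[[i]]$W - lr * gW
                weights[[i]]$b <- weights[[i]]$b - lr * gb
            }
        }
        lossHist[ep] <- epLoss / n
    }
    new("AnnExtractor", weights = weights, config = config,
        tapLayer = config$tapLayer, lossHistory = lossHist)
}

#' @rdname accessors
#' @export
setMethod("featureDim", "AnnExtractor",
    function(x) x@config$widths[x@tapLayer])

setMethod("show", "AnnExtractor", function(object) {
    cat("AnnExtractor: ", object@config$inputDim, " -> ",
        paste(object@config$widths, collapse = " -> "), " -> 1; tap layer ",
        object@tapLayer, " (", featureDim(object), " features)\n", sep = "")
})

#' @rdname compress
#' @export
setMethod("compress", "AnnExtractor", function(object, x) {
    x <- as.matrix(x)
    if (ncol(x) != object@config$inputDim)
        stop("input has ", ncol(x), " columns but the network expects ",
             object@config$inputDim)
    fwd <- annForward(object@weights, x, object@config$leakySlope)
    fwd$acts[[object@tapLayer]]$a
})

#' Persist / restore a trained extractor as JSON
#'
#' @param extractor an [AnnExtractor]
#' @param path file path
#' @return `writeExtractor()` returns `path` invisibly; `readExtractor()`
#'   the reconstructed [AnnExtractor]
#' @export
writeExtractor <- function(extractor, path) {
    stopifnot(is(extractor, "AnnExtractor"))
    obj <- list(config = extractor@config, tapLayer = extractor@tapLayer,
                lossHistory = extractor@lossHistory,
                weights = lapply(extractor@weights, function(l)
                    list(W = apply(l$W, 1L, as.numeric, simplify = FALSE),
                         b = as.numeric(l$b))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeExtractor
#' @export
readExtractor <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    cfg <- obj$config
    for (f in c("inputDim", "hiddenLayers", "tapLayer", "epochs",
                "batchSize", "seed"))
        cfg[[f]] <- as.integer(cfg[[f]])
    cfg$widths <- as.integer(unlist(cfg$widths))
    cfg$learningRate <- as.numeric(cfg$learningRate)
    cfg$leakySlope <- as.numeric(cfg$leakySlope)
    weights <- lapply(obj$weights, function(l)
        list(W = do.call(rbind, lapply(l$W, unlist)), b = unlist(l$b)))
    new("AnnExtractor", weights = weights, config = cfg,
        tapLayer = as.integer(obj$tapLayer),
        lossHistory = as.numeric(unlist(obj$lossHistory)))
}
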
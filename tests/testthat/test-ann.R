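test_that("the halving rule fixes the hidden widths and tap dimension", {
    cfg <- annConfig(inputDim = 242)
    expect_equal(cfg$widths, c(242L, 121L))
    cfg3 <- annConfig(inputDim = 242, hiddenLayers = 3, tapLayer = 3)
    expect_equal(cfg3$widths, c(242L, 121L, 60L))
    set.seed(1)
    x <- matrix(rnorm(5 * 242), 5)
    y <- rep(0:1, length.out = 5)
    ex <- trainANN(x, y, annConfig(inputDim = 242, epochs = 0))
    expect_equal(dim(compress(ex, x)), c(5L, 121L))
    expect_equal(featureDim(ex), 121L)
    ex3 <- trainANN(x, y, annConfig(inputDim = 242, hiddenLayers = 3,
                                    tapLayer = 3, epochs = 0))
    expect_equal(dim(compress(ex3, x)), c(5L, 60L))
    # tap at layer i has width floor(242 / 2^(i-1))
    for (i in 1:3)
        expect_equal(annConfig(242, 3, i)$widths[i], 242L %/% 2L^(i - 1L))
})

test_that("training is deterministic and epochs = 0 is the initialization", {
    set.seed(2)
    x <- matrix(rnorm(40 * 10), 40)
    y <- rep(0:1, each = 20)
    cfg <- annConfig(inputDim = 10, epochs = 5, batchSize = 16, seed = 33)
    ex1 <- trainANN(x, y, cfg)
    ex2 <- trainANN(x, y, cfg)
    expect_identical(ex1@weights, ex2@weights)
    cfg0 <- annConfig(inputDim = 10, epochs = 0, seed = 33)
    ex0a <- trainANN(x, y, cfg0)
    ex0b <- trainANN(x, y, cfg0)
    expect_identical(ex0a@weights, ex0b@weights)
    expect_length(ex0a@lossHistory, 0L)
    # trained weights differ from the initialization
    expect_false(identical(ex1@weights[[1]]$W, ex0a@weights[[1]]$W))
})

test_that("loss decreases on linearly separable data", {
    set.seed(3)
    n <- 200
    x <- matrix(rnorm(n * 8), n)
    y <- as.integer(x[, 1] + x[, 2] > 0)
    ex <- trainANN(x, y, annConfig(inputDim = 8, epochs = 40, seed = 4))
    h <- ex@lossHistory
    expect_lt(h[40], h[1])
    expect_gt(mean(diff(h) < 0), 0.9)   # near-monotone decrease
})

test_that("compression rejects mismatched inputs and handles zero weights", {
    set.seed(4)
    x <- matrix(rnorm(10 * 6), 10)
    ex <- trainANN(x, rep(0:1, 5), annConfig(inputDim = 6, epochs = 0))
    expect_error(compress(ex, x[, 1:5]), "expects 6")
    expect_error(trainANN(x[, 1:5], rep(0:1, 5), annConfig(inputDim = 6)),
                 "expects 6")
    exZero <- ex
    for (i in seq_along(exZero@weights)) {
        exZero@weights[[i]]$W[] <- 0
        exZero@weights[[i]]$b[] <- 0
    }
    act <- compress(exZero, x)
    expect_true(all(act == 0))
})

test_that("extractors round-trip through the JSON archive", {
    set.seed(5)
    x <- matrix(rnorm(30 * 6), 30)
    y <- rep(0:1, 15)
    ex <- trainANN(x, y, annConfig(inputDim = 6, epochs = 3, seed = 7))
    path <- tempfile(fileext = ".json")
    writeExtractor(ex, path)
    ex2 <- readExtractor(path)
    expect_equal(compress(ex2, x), compress(ex, x), tolerance = 1e-12)
    expect_equal(ex2@config$widths, ex@config$widths)
})

test_that("a boosted model on compressed features stays close to raw features", {
    # strongly separable pair data: deterministic compatibility labels
    b <- generateBenchmark(synthConfig(nGpcrs = 30, lengthRange = c(60, 120),
                                       nDrugs = 20, nPairs = 300, beta = 1,
                                       seed = 29))
    wb <- buildWordbooks(b$sequences, seed = 29)
    pf <- assemblePairs(featurizeSequences(b$sequences, wb),
                        drugFeatureMatrix(b$fingerprints), b$pairs)
    x <- featureMatrix(pf)
    y <- pairLabels(pf)
    set.seed(6)
    split <- sample(nrow(x), nrow(x) %/% 2)
    test <- setdiff(seq_len(nrow(x)), split)
    ex <- trainANN(x[split, ], y[split],
                   annConfig(inputDim = ncol(x), seed = 8))
    mRaw <- trainClassifier(x[split, ], y[split], classifierSpec(seed = 9))
    mCmp <- trainClassifier(compress(ex, x[split, ]), y[split],
                            classifierSpec(seed = 9))
    aucRaw <- rocAuc(y[test], predictScores(mRaw, x[test, ]))
    aucCmp <- rocAuc(y[test], predictScores(mCmp, compress(ex, x[test, ])))
    expect_gt(aucCmp, aucRaw - 0.05)
})
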
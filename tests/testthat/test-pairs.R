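makePairFixture <- function(nG = 6, nD = 4, nPairs = 12, seed = 41) {
    seqs <- randomSeqs(nG, len = 80, seed = seed)
    fps <- randomHex(nD, seed = seed + 1)
    names(fps) <- paste0("D", seq_len(nD))
    wb <- buildWordbooks(seqs, seed = seed)
    set.seed(seed + 2)
    pairs <- data.frame(gpcr_id = sample(names(seqs), nPairs, replace = TRUE),
                        drug_id = sample(names(fps), nPairs, replace = TRUE),
                        label = rep_len(c(1L, 0L, 0L), nPairs))
    list(g = featurizeSequences(seqs, wb), d = drugFeatureMatrix(fps),
         pairs = pairs)
}

test_that("pair assembly concatenates receptor and drug blocks to 242 columns", {
    fx <- makePairFixture()
    pf <- assemblePairs(fx$g, fx$d, fx$pairs)
    expect_equal(dim(pf), c(12L, 242L))
    expect_equal(featureDim(pf), 242L)
    i <- 5
    expect_equal(unname(featureMatrix(pf)[i, 1:114]),
                 unname(fx$g[fx$pairs$gpcr_id[i], ]))
    expect_equal(unname(featureMatrix(pf)[i, 115:242]),
                 unname(fx$d[fx$pairs$drug_id[i], ]))
})

test_that("pair assembly handles empty input and surfaces missing ids", {
    fx <- makePairFixture()
    empty <- assemblePairs(fx$g, fx$d, fx$pairs[0, ])
    expect_equal(dim(empty), c(0L, 242L))
    dup <- assemblePairs(fx$g, fx$d, fx$pairs[c(1, 1), ])
    expect_equal(featureMatrix(dup)[1, ], featureMatrix(dup)[2, ])
    bad <- fx$pairs
    bad$gpcr_id[1] <- "nope"
    expect_error(assemblePairs(fx$g, fx$d, bad), "nope")
})

test_that("SMOTE balances classes exactly and keeps originals verbatim", {
    set.seed(51)
    x <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(45 * 4) + 2, 45))
    y <- rep(c(1L, 0L), c(20L, 45L))
    out <- smoteMatrix(x, y, k = 5, seed = 3)
    expect_equal(as.integer(table(out$y)), c(45L, 45L))
    expect_equal(out$x[1:65, ], x)
    expect_identical(out$y[1:65], y)
    expect_equal(sum(out$synthetic), 25L)
    expect_true(all(which(out$synthetic) > 65))
    # determinism
    out2 <- smoteMatrix(x, y, k = 5, seed = 3)
    expect_identical(out$x, out2$x)
})

test_that("synthetic samples interpolate between minority parents", {
    set.seed(52)
    x <- rbind(matrix(rnorm(15 * 3), 15), matrix(rnorm(40 * 3) + 5, 40))
    y <- rep(c(1L, 0L), c(15L, 40L))
    out <- smoteMatrix(x, y, k = 4, seed = 9)
    minority <- x[y == 1L, , drop = FALSE]
    synth <- out$x[out$synthetic, , drop = FALSE]
    onSegment <- function(p) {
        for (i in seq_len(nrow(minority) - 1)) for (j in (i + 1):nrow(minority)) {
            lo <- pmin(minority[i, ], minority[j, ])
            hi <- pmax(minority[i, ], minority[j, ])
            if (all(p >= lo - 1e-9 & p <= hi + 1e-9)) {
                v <- minority[j, ] - minority[i, ]
                w <- p - minority[i, ]
                cr <- sum(v * w) / sqrt(sum(v^2) * sum(w^2) + 1e-300)
                if (sum(w^2) < 1e-18 || cr > 1 - 1e-9) return(TRUE)
            }
        }
        FALSE
    }
    expect_true(all(apply(synth, 1, onSegment)))
})

test_that("the printed-sign variant extrapolates away from the neighbor", {
    set.seed(53)
    x <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(30 * 2) + 8, 30))
    y <- rep(c(1L, 0L), c(10L, 30L))
    out <- smoteMatrix(x, y, k = 3, seed = 7, paperLiteral = TRUE)
    minority <- x[y == 1L, , drop = FALSE]
    lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
    synth <- out$x[out$synthetic, , drop = FALSE]
    outside <- apply(synth, 1, function(p) any(p < lo - 1e-12 | p > hi + 1e-12))
    expect_true(any(outside))
})

test_that("SMOTE reproduces the benchmark imbalance arithmetic", {
    set.seed(54)
    x <- rbind(matrix(rnorm(635 * 4), 635), matrix(rnorm(1225 * 4) + 1, 1225))
    y <- rep(c(1L, 0L), c(635L, 1225L))
    out <- smoteMatrix(x, y, k = 5, seed = 1)
    expect_equal(as.integer(table(out$y)), c(1225L, 1225L))
})

test_that("SMOTE rejects impossible inputs", {
    x <- matrix(rnorm(40), 20)
    expect_error(smoteMatrix(x, rep(1L, 20)), "both classes")
    expect_error(smoteMatrix(x, rep(c(1L, 0L), c(4L, 16L)), k = 5), "exceed k")
})

test_that("the PairFeatures method flags synthetic rows", {
    fx <- makePairFixture(nPairs = 24, seed = 43)
    pf <- assemblePairs(fx$g, fx$d, fx$pairs)
    bal <- smoteOversample(pf, k = 3, seed = 5)
    expect_s4_class(bal, "PairFeatures")
    expect_equal(sum(pairLabels(bal) == 1), sum(pairLabels(bal) == 0))
    expect_true(all(bal@gpcrId[bal@synthetic] == "smote"))
    expect_false(any(bal@synthetic[seq_len(nrow(pf))]))
})
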
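test_that("weighted distance matches its closed form and bounds", {
    expect_equal(weightedDistance(0), 0)
    expect_equal(weightedDistance(1), 0.731059, tolerance = 1e-6)
    expect_lt(abs(weightedDistance(20) - 20), 1e-7)
    expect_error(weightedDistance(-0.1), "nonnegative")
    d <- seq(0.01, 10, by = 0.01)
    w <- weightedDistance(d)
    expect_true(all(diff(w) > 0))       # strictly increasing
    expect_true(all(w < d))             # damped below the raw distance
    expect_gt(weightedDistance(50) / 50, 1 - 1e-9)
})

test_that("two tight far-apart clusters give near-perfect silhouettes", {
    x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
    lab <- c(1, 1, 2, 2)
    s <- wscSamples(x, lab)
    # hand-derived for the first sample: din = (0 + wdist(0.1))/2,
    # dex = (wdist(10) + wdist(10.1))/2
    din <- (0 + oracleWdist(0.1)) / 2
    dex <- (oracleWdist(10) + oracleWdist(10.1)) / 2
    expect_equal(s[1], (dex - din) / dex, tolerance = 1e-12)
    expect_equal(s[1], 0.9974, tolerance = 1e-4)
    expect_equal(wsc(x, lab), mean(oracleWSCSamples(x, lab)), tolerance = 1e-12)
    far <- rbind(matrix(rnorm(100, sd = 0.05), ncol = 2),
                 matrix(rnorm(100, sd = 0.05) + 50, ncol = 2))
    expect_gt(wsc(far, rep(1:2, each = 50)), 0.99)
})

test_that("degenerate clusterings fall back to the zero convention", {
    x <- matrix(c(0, 5, 5.2, 10), ncol = 1)
    s <- wscSamples(x, c(1, 2, 2, 3))  # clusters 1 and 3 are singletons
    expect_equal(s[c(1, 4)], c(0, 0))
    xAll <- matrix(1, 4, 2)
    expect_equal(wsc(xAll, c(1, 1, 2, 2)), 0)   # 0/0 convention
    expect_error(wsc(x, rep(1, 4)), "two clusters")
})

test_that("vectorized silhouettes equal the brute-force oracle", {
    set.seed(11)
    for (rep in 1:6) {
        M <- sample(20:80, 1)
        C <- sample(2:5, 1)
        x <- matrix(rnorm(M * 3), M)
        lab <- sample(seq_len(C), M, replace = TRUE)
        lab[seq_len(C)] <- seq_len(C)      # every cluster non-empty
        for (inc in c(TRUE, FALSE)) {
            got <- wscSamples(x, lab, selfInclusive = inc)
            expect_equal(got, oracleWSCSamples(x, lab, selfInclusive = inc),
                         tolerance = 1e-10)
            expect_true(all(got >= -1 - 1e-12 & got <= 1 + 1e-12))
        }
    }
})

test_that("random labels on a single blob score near zero", {
    set.seed(3)
    x <- matrix(rnorm(200), ncol = 2)
    lab <- sample(1:2, 100, replace = TRUE)
    expect_lte(wsc(x, lab), 0.1)
})

test_that("selectK recovers planted structure and breaks ties downward", {
    cf <- genFragmentClusters(3, nPerCluster = 50, dim = 2, separation = 10,
                              seed = 5)
    sel <- selectK(cf$x, kCandidates = 2:8, seed = 9)
    expect_equal(sel$bestK, 3)
    expect_equal(nrow(sel$profile), 7L)
    expect_equal(sel$profile$WSC[sel$profile$K == 3], max(sel$profile$WSC))
    # single candidate
    expect_equal(selectK(cf$x, kCandidates = 2, seed = 9)$bestK, 2)
    # determinism
    sel2 <- selectK(cf$x, kCandidates = 2:8, seed = 9)
    expect_identical(sel$profile, sel2$profile)
    expect_error(selectK(cf$x[1:5, ], kCandidates = 2:8, seed = 1),
                 "too few fragments")
    expect_error(selectK(cf$x, kCandidates = 1:3, seed = 1), ">= 2")
})

test_that("seeded k-means caps K at the number of distinct points", {
    x <- matrix(rep(c(0, 1), each = 10), ncol = 1)
    km <- seededKmeans(x, 5)
    expect_equal(km$k, 2L)
    expect_equal(sort(km$centers[, 1]), c(0, 1))
    expect_equal(length(km$cluster), 20L)
})
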
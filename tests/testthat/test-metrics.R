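test_that("the metric suite reproduces the independent-test row arithmetic", {
    m <- computeMetrics(104, 234, 26, 26)
    expect_equal(round(100 * m@sn, 1), 80.0)
    expect_equal(round(100 * m@sp, 1), 90.0)
    expect_equal(round(100 * m@acc, 1), 86.7)
    expect_equal(round(100 * m@str, 1), 85.0)
    expect_equal(round(m@mcc, 2), 0.70)
    tab <- metricsTable(m)
    expect_equal(tab$Acc, 100 * 338 / 390)
})

test_that("perfect and degenerate confusion tables hit the boundary values", {
    p <- computeMetrics(50, 50, 0, 0)
    expect_equal(c(p@sn, p@sp, p@acc, p@str, p@mcc), rep(1, 5))
    z <- computeMetrics(0, 50, 0, 50)
    expect_equal(z@sn, 0)
    expect_equal(z@mcc, 0)   # zero-denominator convention
    expect_error(computeMetrics(-1, 2, 3, 4), "nonnegative")
    expect_error(computeMetrics(0, 0, 0, 0), "at least one")
})

test_that("metrics agree with direct formula evaluation on random tables", {
    set.seed(61)
    for (i in 1:1000) {
        cnt <- stats::rpois(4, lambda = 30)
        if (sum(cnt) == 0) next
        m <- computeMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
        tp <- cnt[1]; tn <- cnt[2]; fp <- cnt[3]; fn <- cnt[4]
        sn <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
        sp <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
        den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
        expect_equal(m@acc, (tp + tn) / sum(cnt))
        expect_equal(m@sn, sn)
        expect_equal(m@sp, sp)
        expect_equal(m@str, (sn + sp) / 2)
        expect_equal(m@mcc,
                     ifelse(den > 0, (tp * tn - fp * fn) / sqrt(den), 0))
        expect_true(m@mcc >= -1 && m@mcc <= 1)
    }
})

test_that("thresholding calls the boundary score positive", {
    expect_equal(classifyScores(c(0.49, 0.5, 0.51), 0.5), c(0L, 1L, 1L))
    expect_equal(classifyScores(rep(0, 4), 0.5), rep(0L, 4))
    expect_equal(classifyScores(c(0, 0.1, 1), 0), rep(1L, 3))
})

test_that("the rank AUC matches closed forms and the pairwise oracle", {
    y <- rep(c(1, 0), each = 10)
    expect_equal(rocAuc(y, c(rep(0.9, 10), rep(0.1, 10))), 1)
    expect_equal(rocAuc(y, c(rep(0.1, 10), rep(0.9, 10))), 0)
    expect_error(rocAuc(rep(1, 5), runif(5)), "both classes")
    set.seed(62)
    for (i in 1:10) {
        n <- sample(20:100, 1)
        y <- rbinom(n, 1, 0.4)
        if (length(unique(y)) < 2) next
        s <- round(runif(n), 1)           # deliberately ties
        expect_equal(rocAuc(y, s), oracleAUC(y, s), tolerance = 1e-12)
    }
    set.seed(63)
    y <- rbinom(2000, 1, 0.5)
    expect_lt(abs(rocAuc(y, runif(2000)) - 0.5), 0.03)
})

test_that("the rank AUC agrees with pROC", {
    set.seed(64)
    y <- rbinom(150, 1, 0.4)
    s <- runif(150) + 0.5 * y
    expect_equal(rocAuc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
})

test_that("metrics are invariant to sample permutation", {
    set.seed(65)
    y <- rbinom(80, 1, 0.4)
    s <- runif(80)
    perm <- sample(80)
    m1 <- metricsFromScores(y, s)
    m2 <- metricsFromScores(y[perm], s[perm])
    expect_equal(metricsTable(m1), metricsTable(m2))
})

test_that("ROC points sweep from the origin to (1, 1)", {
    set.seed(66)
    y <- rbinom(50, 1, 0.5)
    s <- runif(50)
    pts <- rocPoints(y, s)
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
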
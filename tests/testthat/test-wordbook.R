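test_that("default word counts give the 114-dimensional representation", {
    seqs <- randomSeqs(12, len = 150, seed = 2)
    wb <- buildWordbooks(seqs, seed = 4)
    expect_equal(featureDim(wb), 114L)
    expect_equal(vapply(wb@books, wordCount, integer(1)),
                 c(A = 20L, B = 16L, C = 62L, D = 16L))
    v <- featurizeGPCR(seqs[[1]], wb)
    expect_length(v, 114L)
    blocks <- split(v, sub("^f_([A-D])_.*$", "\\1", names(v)))
    for (b in blocks) expect_equal(sum(b), 1, tolerance = 1e-9)
    expect_true(all(v >= 0 & v <= 1))
})

test_that("wordbook learning is deterministic given the seed", {
    seqs <- randomSeqs(6, len = 100, seed = 3)
    wb1 <- buildWordbooks(seqs, K = c(B = 5, C = 7, D = 5), seed = 11)
    wb2 <- buildWordbooks(seqs, K = c(B = 5, C = 7, D = 5), seed = 11)
    for (id in c("B", "C", "D"))
        expect_identical(wordMatrix(wb1@books[[id]]),
                         wordMatrix(wb2@books[[id]]))
})

test_that("degenerate input collapses wordbooks to the distinct fragments", {
    wb <- buildWordbooks(c(s = strrep("A", 40)),
                         K = c(B = 5, C = 5, D = 5), seed = 1)
    for (id in c("B", "C", "D"))
        expect_equal(wordCount(wb@books[[id]]), 1L)
    expect_error(buildWordbooks(c(s = "AC"), K = c(B = 2, C = 2, D = 2)),
                 "wordbook C")
})

test_that("composition block reflects residue frequencies", {
    seqs <- randomSeqs(8, len = 90, seed = 6)
    wb <- buildWordbooks(seqs, K = c(B = 4, C = 4, D = 4), seed = 2)
    v <- featurizeGPCR("AAAA", wb)
    blockA <- v[startsWith(names(v), "f_A_")]
    aPos <- which(rownames(wordMatrix(wb@books$A)) == "A")
    expect_equal(unname(blockA[aPos]), 1)
    expect_equal(sum(blockA), 1)
    expect_error(featurizeGPCR("XXXX", wb), "standard")
})

test_that("fragments go to the nearest word, ties to the lowest index", {
    shapes <- wordbookShapes()
    wbB <- new("Wordbook", id = "B", shape = shapes$B,
               words = matrix(c(-1, -1, 1, 1), 2, byrow = TRUE))
    scale <- kyteDoolittleScale()
    aa <- sort(names(scale))
    wbA <- new("Wordbook", id = "A", shape = shapes$A,
               words = matrix(unname(scale[aa]), ncol = 1,
                              dimnames = list(aa, NULL)))
    wbC <- new("Wordbook", id = "C", shape = shapes$C,
               words = matrix(0, 1, 3))
    wbD <- new("Wordbook", id = "D", shape = shapes$D,
               words = matrix(0, 1, 2))
    wbs <- new("WordbookSet", books = list(A = wbA, B = wbB, C = wbC, D = wbD),
               scale = scale, scaleName = "Kyte-Doolittle hydropathy",
               seed = 1L)
    # glycine encodes to -0.4 -> fragments (-0.4, -0.4) are nearer (-1, -1)
    v <- featurizeGPCR("GGGG", wbs)
    expect_equal(unname(v[c("f_B_1", "f_B_2")]), c(1, 0))
    # proline (-1.6) and alanine (1.8): fragment exactly between the words
    # of a symmetric book goes to the first word
    wbTie <- wbs
    wbTie@books$B@words <- matrix(c(-2, -2, 2, 2), 2, byrow = TRUE)
    vTie <- featurizeGPCR("GGGG", wbTie)  # (-0.4,-0.4) nearer (-2,-2)
    expect_equal(unname(vTie[c("f_B_1", "f_B_2")]), c(1, 0))
    # exact float tie: with G encoded as -0.5, the fragment (-0.5,-0.5)
    # is equidistant from (0.5,-0.5) and (-1.5,-0.5) -> first word wins
    tieScale <- scale
    tieScale["G"] <- -0.5
    wbTie@scale <- tieScale
    wbTie@books$B@words <- matrix(c(0.5, -1.5, -0.5, -0.5), 2)
    vT2 <- featurizeGPCR("GGGG", wbTie)
    expect_equal(unname(vT2[c("f_B_1", "f_B_2")]), c(1, 0))
})

test_that("featurization is invariant to duplicating input sequences", {
    seqs <- randomSeqs(5, len = 70, seed = 8)
    wb <- buildWordbooks(seqs, K = c(B = 4, C = 5, D = 4), seed = 3)
    m1 <- featurizeSequences(seqs, wb)
    m2 <- featurizeSequences(c(seqs, seqs[3]), wb)
    expect_equal(m2[3, ], m1[3, ])
    expect_equal(unname(m2[6, ]), unname(m1[3, ]))
})

test_that("wordbook archives round-trip through JSON exactly", {
    seqs <- randomSeqs(5, len = 60, seed = 9)
    wb <- buildWordbooks(seqs, K = c(B = 3, C = 4, D = 3), seed = 5)
    path <- tempfile(fileext = ".json")
    writeWordbooks(wb, path)
    wb2 <- readWordbooks(path)
    expect_equal(featurizeSequences(seqs, wb2), featurizeSequences(seqs, wb),
                 tolerance = 1e-12)
    expect_equal(wordMatrix(wb2@books$C), wordMatrix(wb@books$C),
                 tolerance = 1e-12)
})
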
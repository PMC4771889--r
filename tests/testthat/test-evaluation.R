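test_that("published benchmark counts reproduce the published scores at 3 decimals", {
    noiseless <- confusionScores(confusionFromCounts(32, 860, 4, 4))
    expect_identical(round(unname(noiseless), 3),
                     c(0.889, 0.995, 0.991, 0.884))
    noisy <- confusionScores(confusionFromCounts(32, 845, 19, 4))
    expect_identical(round(unname(noisy), 3),
                     c(0.889, 0.978, 0.974, 0.735))
})

test_that("pairwise confusion counts cover all ordered pairs including self-pairs", {
    set.seed(3)
    for (n in c(3, 6, 10)) {
        a <- SignedNetwork(matrix(sample(-1:1, n * n, TRUE), n, n))
        b <- SignedNetwork(matrix(sample(-1:1, n * n, TRUE), n, n))
        cts <- confusionCounts(confusionMetrics(a, b))
        expect_identical(sum(cts), as.integer(n^2))
    }
    net <- benchmarkNetwork30()
    gold <- goldStandard(net)
    perfect <- confusionMetrics(gold, gold)
    expect_identical(unname(confusionCounts(perfect)),
                     c(36L, 864L, 0L, 0L))
    expect_equal(unname(confusionScores(perfect)), rep(1, 4))
})

test_that("MCC is bounded, symmetric under class swap, and 0 on degenerate tables", {
    set.seed(4)
    for (i in 1:25) {
        cts <- sample(0:50, 4, replace = TRUE)
        m <- confusionScores(
            confusionFromCounts(cts[1], cts[2], cts[3], cts[4]))[["mcc"]]
        swapped <- confusionScores(
            confusionFromCounts(cts[2], cts[1], cts[4], cts[3]))[["mcc"]]
        expect_gte(m, -1)
        expect_lte(m, 1)
        expect_equal(m, swapped, tolerance = 1e-12)
    }
    expect_identical(
        confusionScores(confusionFromCounts(0, 10, 0, 0))[["mcc"]], 0)
})

test_that("sign agreement separates matching and flipped polarities among TPs", {
    gold <- goldStandard(benchmarkNetwork30())
    expect_identical(signAgreement(gold, gold),
                     c(correct = 36L, flipped = 0L))
    s <- signMatrix(gold)
    s[1, 14] <- -s[1, 14]  # flip one true edge's polarity
    flipped <- SignedNetwork(s)
    expect_identical(signAgreement(flipped, gold),
                     c(correct = 35L, flipped = 1L))
    empty <- SignedNetwork(matrix(0, 30, 30))
    expect_identical(signAgreement(empty, gold),
                     c(correct = 0L, flipped = 0L))
    expect_error(confusionMetrics(empty, SignedNetwork(matrix(0, 3, 3))),
                 "same number of genes")
})

test_that("the evaluation report carries counts, scores and sign agreement", {
    gold <- goldStandard(benchmarkNetwork30())
    rep <- evaluationReport(gold, gold)
    expect_named(rep, c("counts", "scores", "signAgreement"))
    expect_identical(rep$counts$tp, 36L)
    expect_equal(rep$scores$mcc, 1)
    f <- tempfile(fileext = ".json")
    evaluationReport(gold, gold, file = f)
    expect_true(file.exists(f))
    back <- jsonlite::read_json(f)
    expect_identical(back$counts$tp, 36L)
})
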
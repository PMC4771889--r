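test_that("the 30-gene benchmark network matches its published parameterization", {
    net <- benchmarkNetwork30()
    w <- weightMatrix(net)
    expect_identical(dim(w), c(30L, 30L))
    expect_identical(sum(w != 0), 36L)
    edges <- benchmarkEdgeTable()
    for (r in seq_len(nrow(edges)))
        expect_identical(w[edges[r, 1], edges[r, 2]], edges[r, 3])
    # every entry not in the edge list is zero
    mask <- matrix(TRUE, 30, 30)
    mask[edges[, 1:2]] <- FALSE
    expect_true(all(w[mask] == 0))
    b <- biasTerms(net)
    expect_equal(b[c(2, 5, 6, 10, 16, 24, 28)], rep(5, 7))
    expect_equal(b[c(15, 17, 27)], rep(-5, 3))
    expect_equal(b[-c(2, 5, 6, 10, 15, 16, 17, 24, 27, 28)],
                 rep(0, 20))
    expect_equal(timeConstants(net), rep(10, 30))
    expect_identical(deltaT(net), 1)
})

test_that("the gold standard reproduces the signed edge set", {
    net <- benchmarkNetwork30()
    gold <- goldStandard(net)
    expect_identical(edgeCount(gold), 36L)
    edges <- benchmarkEdgeTable()
    s <- signMatrix(gold)
    expect_identical(s[edges[, 1:2]], sign(edges[, 3]))
    expect_identical(s[1, 14], -1)   # inhibition of gene 1 by gene 14
    expect_identical(s[26, 28], 1)
    zero <- goldStandard(RNNetwork(matrix(0, 3, 3)))
    expect_identical(edgeCount(zero), 0L)
})

test_that("dataset generation follows the replicate protocol and is seeded", {
    net <- benchmarkNetwork30()
    d <- generateDataset(net, nSeries = 5, nTimepoints = 50, seed = 3)
    expect_s4_class(d, "ExpressionTimeSeries")
    expect_identical(nSeries(d), 5L)
    expect_identical(nTimepoints(d), 50L)
    expect_identical(nGenes(d), 30L)
    a <- SummarizedExperiment::assay(d)
    expect_true(all(a >= 0 & a <= 1))
    d2 <- generateDataset(net, 5, 50, seed = 3)
    expect_identical(seriesMatrices(d), seriesMatrices(d2))
    d3 <- generateDataset(net, 5, 50, seed = 4)
    expect_false(identical(seriesMatrices(d)[[1]][1, ],
                           seriesMatrices(d3)[[1]][1, ]))
    # each series follows the deterministic dynamics from its first row
    m <- seriesMatrices(d)[[2]]
    expect_equal(m, simulateExpression(net, m[1, ], 49),
                 tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("noise injection preserves bounds, scales as requested, and is exact at zero", {
    net <- benchmarkNetwork30()
    d <- generateDataset(net, 2, 25, seed = 1)
    expect_identical(seriesMatrices(addNoise(d, 0, seed = 9)),
                     seriesMatrices(d))
    noisy <- addNoise(d, 0.05, seed = 9)
    m0 <- do.call(rbind, seriesMatrices(d))
    m1 <- do.call(rbind, seriesMatrices(noisy))
    expect_true(all(m1 >= 0 & m1 <= 1))
    # multiplicative Gaussian: E|relative deviation| = sigma * sqrt(2/pi)
    inner <- m0 > 0.05 & m0 < 0.95  # away from clipping
    relDev <- abs(m1[inner] - m0[inner]) / m0[inner]
    expect_equal(mean(relDev), 0.05 * sqrt(2 / pi), tolerance = 0.15)
    big <- addNoise(d, 0.5, seed = 2)
    expect_true(all(do.call(rbind, seriesMatrices(big)) >= 0))
    expect_true(all(do.call(rbind, seriesMatrices(big)) <= 1))
    additive <- addNoise(d, 0.05, seed = 9, model = "additive")
    m2 <- do.call(rbind, seriesMatrices(additive))
    expect_equal(sd((m2 - m0)[inner]), 0.05, tolerance = 0.1)
    expect_error(addNoise(d, -0.1), "non-negative")
})

test_that("the ring toy network oscillates in the responsive sigmoid regime", {
    toy <- toyRingNetwork(5)
    expect_identical(edgeCount(goldStandard(toy)), 6L)
    expect_true(all(rowSums(weightMatrix(toy) != 0) <= 2))
    expect_true(all(abs(weightMatrix(toy)[weightMatrix(toy) != 0]) >= 10))
    tr <- simulateExpression(toy, rep(0.3, 5), 300)
    late <- tr[200:301, ]
    expect_true(all(apply(late, 2, sd) > 0.05))  # sustained, not damped
})
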
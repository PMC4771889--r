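test_that("decoupled fitness equals the hand-computed squared residual on a 2-point series", {
    # one series, T = 2, one regulator: a single transition
    m <- matrix(c(0.4, 0.6,    # regulator gene 1 at t = 1, 2
                  0.2, 0.7),   # target gene 2 at t = 1, 2
                nrow = 2)
    d <- ExpressionTimeSeries(list(m))
    w <- 2; beta <- 0.5; tau <- 2
    pred <- (1 / tau) * (1 / (1 + exp(-(w * 0.4 + beta)))) +
        (1 - 1 / tau) * 0.2
    expect_equal(decoupledFitness(d, 2, 1, c(w, beta, tau)),
                 (pred - 0.7)^2, tolerance = 1e-14)
    expect_gte(decoupledFitness(d, 2, 1, c(-3, 1, 9)), 0)
    expect_identical(decoupledFitness(d, 2, 1, c(NA, 0, 1)), Inf)
    expect_error(decoupledFitness(d, 2, c(1, 1), c(0, 0, 0, 1)),
                 "distinct")
    expect_error(decoupledFitness(d, 2, 1, c(0, 0)), "length")
})

test_that("the generating parameters reproduce their own data to machine zero", {
    net <- benchmarkNetwork30()
    d <- generateDataset(net, 5, 50, seed = 1)
    w <- weightMatrix(net)
    perGene <- vapply(1:30, function(i) {
        regs <- which(w[i, ] != 0)
        decoupledFitness(d, i, regs,
                         c(w[i, regs], biasTerms(net)[i],
                           timeConstants(net)[i]))
    }, numeric(1))
    expect_true(all(perGene < 1e-20))
    expect_equal(sum(perGene), coupledFitness(d, net), tolerance = 1e-20)
})

test_that("tau at the box boundary is clamped, not an error", {
    m <- matrix(runif(8), 4, 2)
    d <- ExpressionTimeSeries(list(m))
    f0 <- decoupledFitness(d, 2, 1, c(1, 0, 0))
    expect_true(is.finite(f0))
    expect_equal(f0, decoupledFitness(d, 2, 1, c(1, 0, 1e-3)),
                 tolerance = 1e-12)
})

test_that("edge calling thresholds weight magnitudes and keeps signs", {
    w <- matrix(0, 3, 3)
    w[1, 2] <- 0.3
    w[2, 3] <- -15
    w[3, 1] <- 0.6
    inf <- new("InferredNetwork", weights = w, bias = numeric(3),
               tau = rep(10, 3), fitness = numeric(3),
               regulators = list(2L, 3L, 1L),
               stopReason = rep("tolerance", 3), edgeThreshold = 0.5)
    called <- callEdges(inf)
    expect_identical(signMatrix(called)[1, 2], 0)    # below threshold
    expect_identical(signMatrix(called)[2, 3], -1)   # inhibitory edge
    expect_identical(signMatrix(called)[3, 1], 1)
    expect_identical(edgeCount(callEdges(inf, threshold = 0.1)), 3L)
    zero <- new("InferredNetwork", weights = matrix(0, 2, 2),
                bias = numeric(2), tau = rep(1, 2), fitness = numeric(2),
                regulators = list(1L, 2L), stopReason = rep("x", 2),
                edgeThreshold = 0.1)
    expect_identical(edgeCount(callEdges(zero)), 0L)
})

test_that("end-to-end inference recovers the ring toy exactly on noiseless data", {
    toy <- toyRingNetwork(5)
    d <- generateDataset(toy, 5, 50, seed = 11)
    inf <- inferNetwork(d, csControl(nNests = 2, nGenerations = 10,
                                     seed = 5),
                        fpaControl(maxIterations = 500))
    expect_true(all(rowSums(weightMatrix(inf) != 0) <= 3))
    called <- callEdges(inf)
    gold <- goldStandard(toy)
    m <- confusionMetrics(called, gold)
    expect_identical(confusionScores(m)[["mcc"]], 1)
    agree <- signAgreement(called, gold)
    expect_identical(agree[["correct"]], 6L)
    expect_identical(agree[["flipped"]], 0L)
})

test_that("single-gene inference is deterministic and matches the search", {
    net <- singleRegulatorNetwork4()
    d <- generateDataset(net, 3, 30, seed = 2)
    csc <- csControl(nNests = 2, nGenerations = 5, seed = 9)
    fpc <- fpaControl(maxIterations = 300)
    g1 <- inferGene(d, 1, csc, fpc)
    g2 <- inferGene(d, 1, csc, fpc)
    expect_identical(g1, g2)
    expect_true(3L %in% g1$regulators)
})
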
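test_that("Levy draws are symmetric, heavy-tailed with the requested exponent, and seeded", {
    set.seed(101)
    s <- levySample(1e6, lambda = 1.5)
    expect_lt(abs(mean(sign(s))), 0.01)        # symmetric about 0
    expect_lt(abs(median(s)), 0.01)
    # tail index: P(|S| > s) ~ s^-lambda, slope between s = 10 and 100
    p10 <- mean(abs(s) > 10)
    p100 <- mean(abs(s) > 100)
    slopeHat <- log10(p10 / p100)
    expect_equal(slopeHat, 1.5, tolerance = 0.15)
    set.seed(7)
    a <- levySample(100)
    set.seed(7)
    expect_identical(levySample(100), a)
    expect_error(levySample(10, lambda = 0.9), "lambda")
    expect_error(levySample(10, lambda = 3.5), "lambda")
})

test_that("pollination steps obey their fixed points and algebra", {
    x <- c(1, 2, 3)
    set.seed(1)
    expect_equal(globalPollinationStep(x, x, 0.1), x)       # at the best
    expect_equal(globalPollinationStep(x, c(5, 5, 5), 0), x) # zero scale
    expect_error(globalPollinationStep(x, 1:2), "dimension")
    set.seed(1)
    expect_equal(localPollinationStep(x, c(4, 4, 4), c(4, 4, 4)), x)
    # result lies on the segment current .. current + (a - b)
    for (i in 1:20) {
        y <- localPollinationStep(c(0, 0), c(1, 2), c(0, 1))
        eps <- y[1] / 1
        expect_gte(eps, 0)
        expect_lte(eps, 1)
        expect_equal(y[2], eps * 1)
    }
    expect_error(localPollinationStep(x, 1:3, 1:2), "dimension")
})

test_that("FPA solves a 5-D sphere to tolerance inside the benchmark box", {
    target <- c(1, -2, 3, -4, 5)
    sphere <- function(x) sum((x - target)^2)
    for (s in c(1, 2, 3)) {
        res <- fpaMinimize(sphere, rep(-25, 5), rep(25, 5),
                           fpaControl(seed = s))
        expect_lt(res$bestFitness, 1e-8)
        expect_identical(res$stopReason, "tolerance")
        expect_lt(res$iterationsRun, 3000L)
        expect_true(all(diff(res$fitnessHistory) <= 0))
        expect_equal(res$bestPosition, target, tolerance = 1e-3)
    }
})

test_that("a constant objective stops by stagnation exactly at the window", {
    res <- fpaMinimize(function(x) 1, c(-1, -1), c(1, 1),
                       fpaControl(stagnationWindow = 50, seed = 4))
    expect_identical(res$stopReason, "stagnation")
    expect_identical(res$iterationsRun, 50L)
})

test_that("FPA respects the box, treats non-finite objectives as +Inf, and is reproducible", {
    lower <- c(2, -3)
    upper <- c(5, -1)
    seen <- new.env()
    seen$bad <- FALSE
    obj <- function(x) {
        if (any(x < lower - 1e-12) || any(x > upper + 1e-12))
            seen$bad <- TRUE
        if (x[1] > 4.5) return(NaN)  # poisoned region
        sum(x^2)
    }
    ctrl <- fpaControl(maxIterations = 200, seed = 11)
    res <- fpaMinimize(obj, lower, upper, ctrl)
    expect_false(seen$bad)
    expect_true(all(res$bestPosition >= lower & res$bestPosition <= upper))
    expect_lte(res$bestPosition[1], 4.5)  # never settles in the NaN zone
    res2 <- fpaMinimize(obj, lower, upper, ctrl)
    expect_identical(res[c("bestPosition", "bestFitness", "stopReason")],
                     res2[c("bestPosition", "bestFitness", "stopReason")])
    # seeded runs leave the caller's RNG stream untouched
    set.seed(99)
    before <- runif(1)
    set.seed(99)
    invisible(fpaMinimize(function(x) sum(x^2), -1, 1,
                          fpaControl(maxIterations = 20, seed = 5)))
    expect_identical(runif(1), before)
})
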
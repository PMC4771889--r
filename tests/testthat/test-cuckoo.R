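test_that("partition initialization covers genes in consecutive blocks", {
    n30 <- initializeNests(30, csControl(nNests = 10, iMax = 3))
    expect_length(n30, 10L)
    regs <- lapply(n30, `[[`, "regulators")
    expect_identical(regs[[1]], 1:3)
    expect_identical(regs[[2]], 4:6)
    expect_identical(regs[[10]], 28:30)
    expect_identical(sort(unlist(regs)), 1:30)  # no repetition

    n8 <- initializeNests(8, csControl(nNests = 2, iMax = 3))
    expect_identical(lapply(n8, `[[`, "regulators"), list(1:3, 4:6))

    n3 <- initializeNests(3, csControl(nNests = 1, iMax = 3))
    expect_identical(n3[[1]]$regulators, 1:3)

    # blocks past the gene count are completed with distinct random genes
    set.seed(1)
    n5 <- initializeNests(5, csControl(nNests = 2, iMax = 3))
    expect_identical(n5[[1]]$regulators, 1:3)
    r2 <- n5[[2]]$regulators
    expect_length(r2, 3L)
    expect_true(all(c(4L, 5L) %in% r2))
    expect_identical(anyDuplicated(r2), 0L)

    expect_error(initializeNests(2, csControl(iMax = 3)), "iMax")
})

test_that("Levy combination moves preserve nest invariants and favour small jumps", {
    ctrl <- csControl(iMax = 3)
    nest <- list(regulators = c(1L, 2L, 3L), params = NULL,
                 fitness = Inf, stopReason = NA_character_)
    set.seed(5)
    ks <- integer(0)
    for (i in 1:4000) {
        moved <- levyMove(nest, 30, ctrl)
        r <- moved$regulators
        expect_length(r, 3L)
        expect_identical(anyDuplicated(r), 0L)
        expect_true(all(r >= 1L & r <= 30L))
        ks <- c(ks, 3L - length(intersect(r, nest$regulators)))
    }
    expect_true(all(ks >= 1L))
    tab <- tabulate(ks, 3)
    expect_gt(tab[1], tab[2])  # k = 1 most frequent ...
    expect_gt(tab[2], tab[3])  # ... k = iMax rarest
})

test_that("abandonment replaces only the worst nests and never the best", {
    ctrl <- csControl(nNests = 4, abandonProb = 1, iMax = 2)
    nests <- lapply(1:4, function(i)
        list(regulators = c(i, i + 4L), params = 1:4,
             fitness = i, stopReason = "tolerance"))
    set.seed(2)
    kept <- abandonWorst(nests, 10, csControl(nNests = 4,
                                              abandonProb = 0, iMax = 2))
    expect_identical(kept, nests)  # p_a = 0: unchanged
    out <- abandonWorst(nests, 10, ctrl)
    fits <- vapply(out, `[[`, numeric(1), "fitness")
    expect_identical(sum(is.finite(fits)), 1L)     # 3 of 4 replaced
    expect_identical(out[[1]], nests[[1]])         # elite survives
    for (nst in out) {
        expect_length(nst$regulators, 2L)
        expect_identical(anyDuplicated(nst$regulators), 0L)
    }
})

test_that("the search recovers a single strong regulator on a 4-gene toy", {
    net <- singleRegulatorNetwork4()
    d <- generateDataset(net, 5, 50, seed = 21)
    csc <- csControl(nNests = 2, nGenerations = 10, seed = 3)
    res <- searchRegulators(d, 1, csc, fpaControl(maxIterations = 500))
    expect_true(3L %in% res$regulators)
    expect_lt(res$fitness, 1e-8)
    wFit <- res$params[match(3L, res$regulators)]
    expect_gt(wFit, 0)  # activation recovered with the generating sign
    res2 <- searchRegulators(d, 1, csc, fpaControl(maxIterations = 500))
    expect_identical(res, res2)  # same seeds, identical nest
})

test_that("an unregulated constant gene yields near-zero weights below tolerance", {
    d <- constantGeneDataset()
    # the one nest holds the two varying peer genes of the constant target
    res <- searchRegulators(d, 3, csControl(nNests = 1, nGenerations = 3,
                                            iMax = 2, seed = 1),
                            fpaControl(maxIterations = 500))
    expect_lt(res$fitness, 1e-8)
    expect_true(all(abs(res$params[1:2]) < 0.1))
})

test_that("generation-best fitness is non-increasing", {
    net <- toyRingNetwork(5)
    d <- generateDataset(net, 2, 20, seed = 2)
    res <- searchRegulators(d, 2,
        csControl(nNests = 2, nGenerations = 6, seed = 8),
        fpaControl(maxIterations = 100))
    expect_true(all(diff(res$history) <= 0))
})
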
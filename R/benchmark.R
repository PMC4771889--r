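#' The 30-gene artificial benchmark network
#'
#' Builds the standard sparse 30-gene RNN benchmark used to validate network
#' inference: 36 regulatory weights of magnitude 10--20, basal bias +5 for
#' genes 2, 5, 6, 10, 16, 24 and 28, -5 for genes 15, 17 and 27, zero
#' otherwise, and a common time constant of 10 with \eqn{\Delta t = 1}. All
#' other weights are zero, so each gene has at most three regulators.
#'
#' @return An [RNNetwork-class] with 30 genes and 36 edges.
#' @examples
#' net <- benchmarkNetwork30()
#' sum(weightMatrix(net) != 0)  # 36
#' @export
benchmarkNetwork30 <- function() {
    edges <- matrix(c(
         1, 14, -15,
         5,  1,  10,
         6,  1, -20,
         7,  2,  15,
         7,  3,  10,
         8,  4,  20,
         9,  5, -20,
         9,  6,  10,
         9, 17,  10,
        10,  7, -10,
        11,  4, -15,
        11,  7,  15,
        11, 22, -15,
        12, 23,  10,
        13,  8,  20,
        14,  9,  15,
        15, 10, -10,
        16, 11,  15,
        16, 12, -15,
        17, 13, -20,
        19, 14, -15,
        20, 15,  10,
        21, 16, -20,
        23, 17, -10,
        24, 15, -15,
        24, 18, -20,
        24, 19,  15,
        25, 20, -10,
        26, 11,  20,
        26, 28,  20,
        27, 24, -15,
        27, 25,  10,
        27, 30,  15,
        28, 25, -15,
        29, 26,  10,
        30, 27,  15
    ), ncol = 3, byrow = TRUE)
    w <- matrix(0, 30, 30)
    w[edges[, 1:2]] <- edges[, 3]
    bias <- numeric(30)
    bias[c(2, 5, 6, 10, 16, 24, 28)] <- 5
    bias[c(15, 17, 27)] <- -5
    RNNetwork(w, bias = bias, tau = rep(10, 30), deltaT = 1)
}

#' Random sparse toy network
#'
#' Generates a small random RNN network for fast tests and demonstrations:
#' each gene receives between 0 and \code{maxRegulators} regulators with
#' weight magnitudes drawn uniformly from \code{weightRange} and random
#' signs.
#'
#' @param nGenes number of genes.
#' @param maxRegulators largest number of regulators per gene (default 2).
#' @param weightRange length-2 numeric, magnitude range of nonzero weights
#'   (default \code{c(10, 20)}; strong weights give clearly identifiable
#'   dynamics).
#' @param tau common time constant (default 10).
#' @param biasValues values the per-gene bias is sampled from (default
#'   \code{c(-5, 0, 5)}).
#' @param seed integer seed controlling all draws.
#' @return An [RNNetwork-class] object.
#' @examples
#' toy <- randomSparseNetwork(5, seed = 1)
#' @export
randomSparseNetwork <- function(nGenes, maxRegulators = 2,
                                weightRange = c(10, 20), tau = 10,
                                biasValues = c(-5, 0, 5), seed = 1) {
    stopifnot(nGenes >= 2, maxRegulators >= 0, maxRegulators < nGenes)
    .withSeed(seed, {
        w <- matrix(0, nGenes, nGenes)
        for (i in seq_len(nGenes)) {
            k <- sample(0:maxRegulators, 1L)
            if (k > 0L) {
                regs <- .sampleVec(setdiff(seq_len(nGenes), i), k)
                w[i, regs] <- sample(c(-1, 1), k, replace = TRUE) *
                    runif(k, weightRange[1], weightRange[2])
            }
        }
        bias <- if (length(biasValues) == 1L) rep(biasValues, nGenes)
                else sample(biasValues, nGenes, replace = TRUE)
        RNNetwork(w, bias = bias, tau = rep(tau, nGenes), deltaT = 1)
    })
}

#' Deterministic ring-oscillator toy network
#'
#' A small hand-designed network for fast end-to-end tests: the genes form
#' a regulatory ring (gene \eqn{i} driven by gene \eqn{i-1}, gene 1 by
#' gene N) with alternating activation/inhibition, and gene 4 receives a
#' second inhibitory regulator. Each gene's bias is set to minus half the
#' sum of its incoming weights, which centres the sigmoid argument around
#' zero over the \eqn{[0,1]} expression range, so regulation operates in
#' the responsive (non-saturated) part of the sigmoid; the negative
#' feedback around the ring keeps the dynamics oscillating instead of
#' collapsing to a fixed point. Both properties make the regulator
#' identities recoverable from the trajectories. All weight magnitudes
#' are at least 10, and no gene has more than 2 regulators.
#'
#' @param nGenes number of genes, at least 5 (default 5).
#' @return An [RNNetwork-class] object with \code{nGenes + 1} edges.
#' @examples
#' toy <- toyRingNetwork(5)
#' edgeCount(goldStandard(toy))  # 6
#' @export
toyRingNetwork <- function(nGenes = 5) {
    stopifnot(nGenes >= 5)
    w <- matrix(0, nGenes, nGenes)
    for (i in seq_len(nGenes)) {
        j <- if (i == 1L) nGenes else i - 1L
        w[i, j] <- if (i %% 2L == 0L) 10 else -12
    }
    w[4L, 2L] <- -10  # one two-regulator gene
    bias <- -rowSums(w) / 2
    RNNetwork(w, bias = bias, tau = rep(10, nGenes), deltaT = 1)
}

#' Generate replicate training time series from an RNN network
#'
#' Each series starts from an independently drawn initial state, uniform on
#' \eqn{[0,1]^N}, and follows the deterministic RNN dynamics. The defaults
#' (5 series of 50 time points) are the benchmark training protocol for the
#' 30-gene network.
#'
#' @param network an [RNNetwork-class] object.
#' @param nSeries number of replicate series (default 5).
#' @param nTimepoints time points per series, at least 2 (default 50).
#' @param seed integer seed for the initial states.
#' @return An [ExpressionTimeSeries-class] with M = \code{nSeries},
#'   T = \code{nTimepoints}.
#' @examples
#' d <- generateDataset(benchmarkNetwork30(), nSeries = 2,
#'                      nTimepoints = 10, seed = 1)
#' nSeries(d); nTimepoints(d)
#' @export
generateDataset <- function(network, nSeries = 5, nTimepoints = 50,
                            seed = 1) {
    stopifnot(is(network, "RNNetwork"), nSeries >= 1, nTimepoints >= 2)
    mats <- .withSeed(seed, {
        lapply(seq_len(nSeries), function(k) {
            init <- runif(nGenes(network))
            simulateExpression(network, init, nTimepoints - 1L)
        })
    })
    ExpressionTimeSeries(mats, geneNames = geneNames(network))
}

#' Inject measurement noise into an expression dataset
#'
#' Perturbs every expression value and clips the result back to
#' \eqn{[0, 1]}. The default, multiplicative Gaussian noise, replaces each
#' value \eqn{x} by \eqn{x (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \sigma^2)}, \eqn{\sigma} = \code{noiseLevel} --
#' the usual reading of "x\% noise" on expression data as a relative
#' perturbation. Additive Gaussian noise
#' (\eqn{x + \epsilon}) is available as an alternative.
#'
#' @param dataset an [ExpressionTimeSeries-class] object.
#' @param noiseLevel non-negative noise fraction; 0.05 is "5\% noise". Zero
#'   returns the input values unchanged.
#' @param seed integer seed.
#' @param model \code{"multiplicative"} (default) or \code{"additive"}.
#' @return A perturbed [ExpressionTimeSeries-class] with all values in
#'   \eqn{[0, 1]}.
#' @examples
#' d <- generateDataset(benchmarkNetwork30(), 1, 10, seed = 1)
#' noisy <- addNoise(d, 0.05, seed = 2)
#' @export
addNoise <- function(dataset, noiseLevel, seed = 1,
                     model = c("multiplicative", "additive")) {
    stopifnot(is(dataset, "ExpressionTimeSeries"))
    model <- match.arg(model)
    if (!is.finite(noiseLevel) || noiseLevel < 0)
        stop("'noiseLevel' must be a non-negative number")
    mats <- seriesMatrices(dataset)
    if (noiseLevel > 0) {
        mats <- .withSeed(seed, {
            lapply(mats, function(m) {
                eps <- matrix(rnorm(length(m), 0, noiseLevel),
                              nrow(m), ncol(m))
                out <- if (model == "multiplicative") m * (1 + eps)
                       else m + eps
                pmin(pmax(out, 0), 1)
            })
        })
    }
    ExpressionTimeSeries(mats, geneNames = geneNames(dataset))
}

#' Gold-standard signed network of a generating model
#'
#' Reduces an RNN network to its biologically meaningful content: the sign
#' pattern of the weight matrix (activation / inhibition / none).
#'
#' @param network an [RNNetwork-class] object.
#' @return A [SignedNetwork-class] object.
#' @examples
#' gold <- goldStandard(benchmarkNetwork30())
#' edgeCount(gold)  # 36
#' @export
goldStandard <- function(network) {
    stopifnot(is(network, "RNNetwork"))
    SignedNetwork(network@weights, geneNames = geneNames(network))
}
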
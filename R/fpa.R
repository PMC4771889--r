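#' Heavy-tailed Levy-flight step draws
#'
#' Samples symmetric steps whose tail decays as \eqn{|s|^{-\lambda}} using
#' Mantegna's construction: \eqn{s = u / |v|^{1/\lambda}} with
#' \eqn{u \sim N(0, \sigma_u^2)}, \eqn{v \sim N(0, 1)} and
#' \deqn{\sigma_u = \left[\frac{\Gamma(1+\lambda)\sin(\pi\lambda/2)}
#'   {\Gamma((1+\lambda)/2)\,\lambda\,2^{(\lambda-1)/2}}\right]^{1/\lambda}.}
#' This is the de facto standard realization of the Levy-stable step
#' distribution in Cuckoo Search and Flower Pollination implementations:
#' mostly small moves with occasional very large jumps.
#'
#' Draws consume the current R random number stream; seed with
#' \code{set.seed()} for reproducibility.
#'
#' @param n number of draws.
#' @param lambda tail exponent, in (1, 3]; default 1.5.
#' @return Numeric vector of \code{n} heavy-tailed steps, symmetric about 0.
#' @examples
#' set.seed(1)
#' summary(levySample(1000))
#' @export
levySample <- function(n, lambda = 1.5) {
    if (!is.finite(lambda) || lambda <= 1 || lambda > 3)
        stop("'lambda' must lie in (1, 3]")
    sigmaU <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
        (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
    u <- rnorm(n, 0, sigmaU)
    v <- rnorm(n)
    u / abs(v)^(1 / lambda)
}

#' Global pollination move
#'
#' Moves a solution towards the population's best along per-dimension
#' Levy-flight draws: \code{current + stepScale * L * (best - current)},
#' with \code{L} a fresh Levy draw for every dimension. The caller is
#' responsible for clipping the result to the search box.
#'
#' @param current numeric position vector.
#' @param best numeric position of the current global best (same length).
#' @param stepScale positive step-scale factor \eqn{\gamma}.
#' @param lambda Levy tail exponent.
#' @return The proposed position (unclipped).
#' @export
globalPollinationStep <- function(current, best, stepScale = 0.1,
                                  lambda = 1.5) {
    if (length(current) != length(best))
        stop("'current' and 'best' must have the same dimension")
    current + stepScale * levySample(length(current), lambda) *
        (best - current)
}

#' Local pollination move
#'
#' Moves a solution along the difference of two population peers scaled by
#' a single uniform draw: \code{current + eps * (peerA - peerB)} with
#' \code{eps ~ Uniform[0, 1]} (one scalar draw per update, so the result
#' lies on the segment between \code{current} and
#' \code{current + (peerA - peerB)}).
#'
#' @param current numeric position vector.
#' @param peerA,peerB positions of two population members (same length as
#'   \code{current}).
#' @return The proposed position (unclipped).
#' @export
localPollinationStep <- function(current, peerA, peerB) {
    if (length(current) != length(peerA) ||
        length(current) != length(peerB))
        stop("all positions must have the same dimension")
    current + runif(1) * (peerA - peerB)
}

#' Control settings for the Flower Pollination Algorithm
#'
#' @param populationSize number of flowers (default 25).
#' @param switchProb probability of taking the LOCAL pollination step
#'   (default 0.8, slightly biased towards local pollination; the global
#'   Levy step is taken with probability \code{1 - switchProb}).
#' @param levyExponent Levy tail exponent for global steps (default 1.5).
#' @param stepScale global-step scale factor \eqn{\gamma} (default 0.1).
#' @param maxIterations iteration cap (default 3000).
#' @param fitnessTolerance absolute fitness level that stops the run
#'   immediately (default 1e-8).
#' @param stagnationWindow iterations over which improvement is measured
#'   for the second stopping rule (default 200).
#' @param stagnationTolerance minimum improvement over the window; less
#'   stops the run (default 1e-10).
#' @param seed optional integer seed; if given, the run is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return A list of class \code{fpaControl}.
#' @export
fpaControl <- function(populationSize = 25, switchProb = 0.8,
                       levyExponent = 1.5, stepScale = 0.1,
                       maxIterations = 3000, fitnessTolerance = 1e-8,
                       stagnationWindow = 200, stagnationTolerance = 1e-10,
                       seed = NULL) {
    stopifnot(populationSize >= 4, switchProb >= 0, switchProb <= 1,
              stepScale > 0, maxIterations >= 1, fitnessTolerance > 0,
              stagnationWindow >= 1, stagnationTolerance > 0)
    structure(list(
        populationSize = as.integer(populationSize),
        switchProb = switchProb, levyExponent = levyExponent,
        stepScale = stepScale, maxIterations = as.integer(maxIterations),
        fitnessTolerance = fitnessTolerance,
        stagnationWindow = as.integer(stagnationWindow),
        stagnationTolerance = stagnationTolerance, seed = seed
    ), class = "fpaControl")
}

#' Minimize a bound-constrained objective with the Flower Pollination
#' Algorithm
#'
#' Population-based continuous minimizer. Flowers are initialized uniformly
#' in the box; each iteration every flower takes the local pollination step
#' with probability \code{switchProb} and the global Levy-flight step
#' otherwise, out-of-box coordinates are clipped, and a move is accepted
#' only if it does not worsen that flower's fitness (so the best-so-far
#' fitness is non-increasing). The run stops when the best fitness drops
#' below \code{fitnessTolerance}, when the improvement over the last
#' \code{stagnationWindow} iterations falls below
#' \code{stagnationTolerance}, or at \code{maxIterations}.
#'
#' Objectives returning non-finite values are treated as +Inf fitness.
#'
#' @param objective function mapping a numeric vector to a single numeric
#'   fitness (lower is better).
#' @param lower,upper numeric vectors defining the search box.
#' @param control an [fpaControl()] list.
#' @return A list with elements \code{bestPosition}, \code{bestFitness},
#'   \code{iterationsRun}, \code{stopReason} (one of \code{"tolerance"},
#'   \code{"stagnation"}, \code{"maxIterations"}) and
#'   \code{fitnessHistory} (best fitness after each iteration,
#'   non-increasing).
#' @examples
#' res <- fpaMinimize(function(x) sum((x - 1)^2), rep(-5, 3), rep(5, 3),
#'                    fpaControl(maxIterations = 500, seed = 1))
#' res$stopReason
#' @export
fpaMinimize <- function(objective, lower, upper, control = fpaControl()) {
    stopifnot(is.function(objective), length(lower) == length(upper),
              all(is.finite(lower)), all(is.finite(upper)),
              all(lower <= upper))
    .withSeed(control$seed,
              .fpaRun(objective, as.numeric(lower), as.numeric(upper),
                      control))
}

.fpaRun <- function(objective, lower, upper, control) {
    d <- length(lower)
    np <- control$populationSize
    f <- function(x) {
        v <- objective(x)
        if (!is.finite(v)) Inf else v
    }
    clip <- function(x) pmin(pmax(x, lower), upper)

    pop <- matrix(runif(np * d, rep(lower, each = np),
                        rep(upper, each = np)), np, d)
    fit <- apply(pop, 1L, f)
    bestIdx <- which.min(fit)
    bestPos <- pop[bestIdx, ]
    bestFit <- fit[bestIdx]

    history <- numeric(control$maxIterations)
    initBest <- bestFit
    stopReason <- "maxIterations"
    t <- 0L
    while (t < control$maxIterations) {
        t <- t + 1L
        for (i in seq_len(np)) {
            cand <- if (runif(1) < control$switchProb) {
                jk <- sample.int(np, 2L)
                localPollinationStep(pop[i, ], pop[jk[1L], ], pop[jk[2L], ])
            } else {
                globalPollinationStep(pop[i, ], bestPos, control$stepScale,
                                      control$levyExponent)
            }
            cand <- clip(cand)
            candFit <- f(cand)
            if (candFit <= fit[i]) {
                pop[i, ] <- cand
                fit[i] <- candFit
                if (candFit < bestFit) {
                    bestFit <- candFit
                    bestPos <- cand
                }
            }
        }
        history[t] <- bestFit
        if (bestFit < control$fitnessTolerance) {
            stopReason <- "tolerance"
            break
        }
        if (t >= control$stagnationWindow) {
            ref <- if (t == control$stagnationWindow) initBest
                   else history[t - control$stagnationWindow]
            if (ref - bestFit < control$stagnationTolerance) {
                stopReason <- "stagnation"
                break
            }
        }
    }
    list(bestPosition = bestPos, bestFitness = bestFit,
         iterationsRun = t, stopReason = stopReason,
         fitnessHistory = history[seq_len(t)])
}
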
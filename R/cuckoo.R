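#' Control settings for the Cuckoo Search over regulator combinations
#'
#' @param nNests number of nests, i.e. candidate regulator combinations
#'   kept per generation (default 10: with \code{iMax = 3} the partition
#'   initialization then covers all 30 benchmark genes exactly once).
#' @param abandonProb fraction of worst nests replaced by fresh random
#'   combinations each generation (default 0.25, the canonical value).
#' @param levyExponent Levy tail exponent for combinatorial moves
#'   (default 1.5).
#' @param stepScale step-size factor \eqn{\alpha} applied to the Levy draw
#'   before it is turned into a replacement count (default 1).
#' @param nGenerations outer search generations (default 30).
#' @param iMax regulator cap: every nest holds exactly \code{iMax} distinct
#'   candidate regulator genes (default 3; sparsity below the cap is
#'   realized through near-zero fitted weights).
#' @param seed master seed of the search.
#' @return A list of class \code{csControl}.
#' @export
csControl <- function(nNests = 10, abandonProb = 0.25, levyExponent = 1.5,
                      stepScale = 1, nGenerations = 30, iMax = 3,
                      seed = 1) {
    stopifnot(nNests >= 1, abandonProb >= 0, abandonProb <= 1,
              stepScale > 0, nGenerations >= 1, iMax >= 1)
    structure(list(
        nNests = as.integer(nNests), abandonProb = abandonProb,
        levyExponent = levyExponent, stepScale = stepScale,
        nGenerations = as.integer(nGenerations), iMax = as.integer(iMax),
        seed = seed
    ), class = "csControl")
}

#' Deterministic partition initialization of regulator nests
#'
#' Nest k starts with the consecutive gene block
#' \eqn{((k-1) i_{max} + 1, \ldots, k\, i_{max})} while gene indices
#' remain, so that (for \code{nNests * iMax <= nGenes}) every gene appears
#' in exactly one initial nest -- covering all candidate regulators without
#' repetition. If the blocks run past \code{nGenes}, the remaining slots
#' are filled with random distinct genes drawn from the current RNG stream.
#'
#' @param nGenes number of genes in the system (must be at least
#'   \code{iMax}).
#' @param control a [csControl()] list.
#' @return A list of \code{nNests} nests; each nest is a list with fields
#'   \code{regulators} (integer vector of length \code{iMax}),
#'   \code{params} (NULL until evaluated), \code{fitness} (Inf until
#'   evaluated) and \code{stopReason}.
#' @examples
#' n <- initializeNests(30, csControl(nNests = 10, iMax = 3))
#' n[[1]]$regulators  # 1 2 3
#' @export
initializeNests <- function(nGenes, control = csControl()) {
    if (nGenes < control$iMax)
        stop("'nGenes' must be at least the regulator cap iMax")
    lapply(seq_len(control$nNests), function(k) {
        lo <- (k - 1L) * control$iMax + 1L
        hi <- k * control$iMax
        regs <- seq(lo, min(hi, nGenes))
        regs <- regs[regs <= nGenes]
        if (length(regs) < control$iMax) {
            pool <- setdiff(seq_len(nGenes), regs)
            regs <- c(regs, .sampleVec(pool, control$iMax - length(regs)))
        }
        .newNest(as.integer(regs))
    })
}

.newNest <- function(regulators) {
    list(regulators = regulators, params = NULL, fitness = Inf,
         stopReason = NA_character_)
}

.randomNest <- function(nGenes, iMax) {
    .newNest(sort(.sampleVec(seq_len(nGenes), iMax)))
}

#' Levy-flight move in regulator-combination space
#'
#' Proposes a new combination from an existing nest: the number of
#' regulator slots replaced, \eqn{k}, is derived from a Levy draw as
#' \code{min(iMax, max(1, round(|stepScale * L|)))} -- mostly 1, rarely
#' larger, preserving the "small steps with occasional big jumps"
#' character of Levy flights in the discrete space -- and the chosen slots
#' are replaced by uniformly drawn genes not already in the nest.
#'
#' @param nest a nest as produced by [initializeNests()].
#' @param nGenes number of genes in the system.
#' @param control a [csControl()] list.
#' @return A new unevaluated nest satisfying the nest invariants
#'   (\code{iMax} distinct gene indices in \code{1..nGenes}).
#' @export
levyMove <- function(nest, nGenes, control = csControl()) {
    iMax <- control$iMax
    L <- levySample(1L, control$levyExponent)
    k <- min(iMax, max(1L, round(abs(control$stepScale * L))))
    k <- min(k, nGenes - iMax)  # cannot swap in more genes than exist
    if (k < 1L) return(.newNest(nest$regulators))
    slots <- .sampleVec(seq_len(iMax), k)
    pool <- setdiff(seq_len(nGenes), nest$regulators)
    regs <- nest$regulators
    regs[slots] <- .sampleVec(pool, k)
    .newNest(sort(as.integer(regs)))
}

#' Replace the worst nests by fresh random combinations
#'
#' Emulates host birds abandoning parasitized nests: the worst
#' \code{ceiling(abandonProb * nNests)} nests (highest fitness) are each
#' replaced by a fresh random combination; the best nest is never
#' abandoned. Fresh nests are unevaluated (fitness Inf).
#'
#' @param nests a list of evaluated nests.
#' @param nGenes number of genes in the system.
#' @param control a [csControl()] list.
#' @return The updated list of nests.
#' @export
abandonWorst <- function(nests, nGenes, control = csControl()) {
    n <- length(nests)
    nAb <- min(ceiling(control$abandonProb * n), n - 1L)
    if (nAb < 1L) return(nests)
    ord <- order(vapply(nests, `[[`, numeric(1), "fitness"),
                 decreasing = TRUE)
    worst <- ord[seq_len(nAb)]
    for (i in worst)
        nests[[i]] <- .randomNest(nGenes, control$iMax)
    nests
}

#' Train the RNN parameters of one regulator combination
#'
#' Fits the \code{(weights, bias, tau)} parameters of the decoupled
#' single-gene RNN for a fixed regulator combination by Flower Pollination
#' minimization of the one-step-ahead squared error. The FPA seed is
#' derived deterministically from \code{masterSeed}, the target gene and
#' the sorted combination, so a given combination always trains
#' identically regardless of when or where it is proposed -- the property
#' that makes the outer search reproducible and memoizable.
#'
#' @param dataset an [ExpressionTimeSeries-class] object.
#' @param targetGene 1-based target gene index.
#' @param regulators integer vector of distinct regulator indices.
#' @param fpaCtrl an [fpaControl()] list (its \code{seed} field is
#'   overridden by the derived seed).
#' @param bounds a [searchBounds()] box for \code{(weights, bias, tau)}.
#' @param masterSeed integer master seed.
#' @return A list with \code{fitness}, \code{params}, \code{stopReason}
#'   and \code{iterations}.
#' @export
nestFitness <- function(dataset, targetGene, regulators,
                        fpaCtrl = fpaControl(maxIterations = 500),
                        bounds = searchBounds("artificial",
                                              length(regulators)),
                        masterSeed = 1) {
    obj <- .decoupledObjective(dataset, targetGene, regulators)
    ctrl <- fpaCtrl
    ctrl$seed <- .seedHash(masterSeed, targetGene, sort(regulators))
    res <- fpaMinimize(obj, bounds$lower, bounds$upper, ctrl)
    list(fitness = res$bestFitness, params = res$bestPosition,
         stopReason = res$stopReason, iterations = res$iterationsRun)
}

#' Cuckoo Search for the best regulator combination of one gene
#'
#' The outer combinatorial search: nests (candidate combinations of
#' \code{iMax} regulator genes) are initialized by the deterministic
#' partition rule, then evolved for \code{nGenerations} rounds of
#' Levy-flight combination moves, FPA training of each proposed
#' combination, greedy replacement (a nest adopts a proposal only if its
#' trained fitness is no worse) and abandonment of the worst nests. Nest
#' fitness is memoized by combination, so re-proposed combinations are not
#' re-trained. The search stops early as soon as the best nest's fitness
#' falls below \code{fpaCtrl$fitnessTolerance}.
#'
#' @inheritParams nestFitness
#' @param csCtrl a [csControl()] list; its \code{seed} is the master seed.
#' @param fpaCtrl an [fpaControl()] list for the inner fits.
#' @return The best nest: a list with \code{regulators}, \code{params},
#'   \code{fitness}, \code{stopReason} (of its FPA fit),
#'   \code{generations} run and \code{history} of per-generation best
#'   fitness (non-increasing).
#' @export
searchRegulators <- function(dataset, targetGene, csCtrl = csControl(),
                             fpaCtrl = fpaControl(maxIterations = 500),
                             bounds = searchBounds("artificial",
                                                   csCtrl$iMax)) {
    stopifnot(is(dataset, "ExpressionTimeSeries"))
    n <- nGenes(dataset)
    if (targetGene < 1L || targetGene > n)
        stop("'targetGene' out of range")
    masterSeed <- if (is.null(csCtrl$seed)) 1L else csCtrl$seed

    memo <- new.env(parent = emptyenv())
    evalNest <- function(nest) {
        key <- paste(nest$regulators, collapse = ".")
        hit <- memo[[key]]
        if (is.null(hit)) {
            hit <- nestFitness(dataset, targetGene, nest$regulators,
                               fpaCtrl, bounds, masterSeed)
            memo[[key]] <- hit
        }
        nest$params <- hit$params
        nest$fitness <- hit$fitness
        nest$stopReason <- hit$stopReason
        nest
    }

    .withSeed(.seedHash(masterSeed, targetGene, 7919L), {
        nests <- lapply(initializeNests(n, csCtrl), evalNest)
        best <- nests[[which.min(vapply(nests, `[[`, numeric(1),
                                        "fitness"))]]
        history <- numeric(csCtrl$nGenerations)
        gen <- 0L
        while (gen < csCtrl$nGenerations &&
               best$fitness >= fpaCtrl$fitnessTolerance) {
            gen <- gen + 1L
            for (i in seq_along(nests)) {
                cand <- evalNest(levyMove(nests[[i]], n, csCtrl))
                if (cand$fitness <= nests[[i]]$fitness)
                    nests[[i]] <- cand
                if (cand$fitness < best$fitness) best <- cand
            }
            if (best$fitness < fpaCtrl$fitnessTolerance) {
                history[gen] <- best$fitness
                break
            }
            nests <- abandonWorst(nests, n, csCtrl)
            nests <- lapply(nests, function(x)
                if (is.finite(x$fitness)) x else evalNest(x))
            fits <- vapply(nests, `[[`, numeric(1), "fitness")
            if (min(fits) < best$fitness) best <- nests[[which.min(fits)]]
            history[gen] <- best$fitness
        }
        best$generations <- gen
        best$history <- history[seq_len(gen)]
        best
    })
}
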
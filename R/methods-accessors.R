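#' @describeIn RNNetwork number of genes
#' @param x an object of the documented class.
#' @export
setMethod("nGenes", "RNNetwork", function(x) nrow(x@weights))

#' @describeIn RNNetwork gene labels
#' @export
setMethod("geneNames", "RNNetwork", function(x) rownames(x@weights))

#' @describeIn RNNetwork weight matrix
#' @export
setMethod("weightMatrix", "RNNetwork", function(x) x@weights)

#' @describeIn RNNetwork bias terms
#' @export
setMethod("biasTerms", "RNNetwork", function(x) x@bias)

#' @describeIn RNNetwork time constants
#' @export
setMethod("timeConstants", "RNNetwork", function(x) x@tau)

#' Simulation time step of an RNNetwork
#'
#' @param x an [RNNetwork-class] object.
#' @return A single positive numeric.
#' @export
deltaT <- function(x) x@deltaT

#' @describeIn ExpressionTimeSeries number of genes
#' @export
setMethod("nGenes", "ExpressionTimeSeries", function(x) nrow(x))

#' @describeIn ExpressionTimeSeries gene labels
#' @export
setMethod("geneNames", "ExpressionTimeSeries", function(x) rownames(x))

#' @describeIn ExpressionTimeSeries number of replicate series
#' @export
setMethod("nSeries", "ExpressionTimeSeries",
    function(x) length(unique(SummarizedExperiment::colData(x)$series)))

#' @describeIn ExpressionTimeSeries number of time points per series
#' @export
setMethod("nTimepoints", "ExpressionTimeSeries",
    function(x) max(SummarizedExperiment::colData(x)$time))

#' @describeIn ExpressionTimeSeries list of T x N per-series matrices
#' @export
setMethod("seriesMatrices", "ExpressionTimeSeries", function(x) {
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x, "expr")
    lapply(unique(cd$series), function(s) {
        sel <- which(cd$series == s)
        sel <- sel[order(cd$time[sel])]
        m <- t(a[, sel, drop = FALSE])
        rownames(m) <- NULL
        m
    })
})

#' @describeIn SignedNetwork number of genes
#' @export
setMethod("nGenes", "SignedNetwork", function(x) nrow(x@sign))

#' @describeIn SignedNetwork gene labels
#' @export
setMethod("geneNames", "SignedNetwork", function(x) rownames(x@sign))

#' @describeIn SignedNetwork the sign matrix
#' @export
setMethod("signMatrix", "SignedNetwork", function(x) x@sign)

#' @describeIn SignedNetwork number of directed edges
#' @export
setMethod("edgeCount", "SignedNetwork", function(x) sum(x@sign != 0))

#' @describeIn SignedNetwork edge list (regulator, target, sign)
#' @export
setMethod("edgeList", "SignedNetwork", function(x) {
    idx <- which(x@sign != 0, arr.ind = TRUE)
    df <- data.frame(
        regulator = as.integer(idx[, "col"]),
        target = as.integer(idx[, "row"]),
        sign = ifelse(x@sign[idx] > 0, "+", "-"),
        stringsAsFactors = FALSE
    )
    df[order(df$regulator, df$target), , drop = FALSE]
})

#' @describeIn InferredNetwork number of genes
#' @export
setMethod("nGenes", "InferredNetwork", function(x) nrow(x@weights))

#' @describeIn InferredNetwork gene labels
#' @export
setMethod("geneNames", "InferredNetwork", function(x) rownames(x@weights))

#' @describeIn InferredNetwork fitted weight matrix
#' @export
setMethod("weightMatrix", "InferredNetwork", function(x) x@weights)

#' @describeIn InferredNetwork fitted bias terms
#' @export
setMethod("biasTerms", "InferredNetwork", function(x) x@bias)

#' @describeIn InferredNetwork fitted time constants
#' @export
setMethod("timeConstants", "InferredNetwork", function(x) x@tau)

#' Per-gene training error of an inferred network
#'
#' @param x an [InferredNetwork-class] object.
#' @return A numeric vector of N squared-error fitness values.
#' @export
geneFitness <- function(x) x@fitness

#' Selected regulator sets of an inferred network
#'
#' @param x an [InferredNetwork-class] object.
#' @return A list of N integer vectors (1-based gene indices).
#' @export
geneRegulators <- function(x) x@regulators

#' Confusion counts
#'
#' @param x a [ConfusionMetrics-class] object.
#' @return A named integer vector with elements \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}.
#' @export
confusionCounts <- function(x) {
    stopifnot(is(x, "ConfusionMetrics"))
    c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn)
}

#' Derived confusion scores
#'
#' @param x a [ConfusionMetrics-class] object.
#' @return A named numeric vector with elements \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, \code{mcc}.
#' @export
confusionScores <- function(x) {
    stopifnot(is(x, "ConfusionMetrics"))
    c(sensitivity = x@sensitivity, specificity = x@specificity,
      accuracy = x@accuracy, mcc = x@mcc)
}
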
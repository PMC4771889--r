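#' Discrete-time recurrent neural network model of a gene network
#'
#' An \code{RNNetwork} holds the full parameterization of the RNN gene model:
#' the next expression value of gene \eqn{i} is
#' \deqn{e_i(t+\Delta t) = \frac{\Delta t}{\tau_i}
#'   f\Big(\sum_j w_{ij} e_j(t) + \beta_i\Big) +
#'   \Big(1 - \frac{\Delta t}{\tau_i}\Big) e_i(t),}
#' with \eqn{f} the logistic sigmoid. Entry \code{weights[i, j]} is the signed
#' strength with which gene \eqn{j} regulates gene \eqn{i} (positive =
#' activation, negative = inhibition, zero = no regulation), \code{bias[i]} is
#' the basal expression term and \code{tau[i]} the time constant controlling
#' how fast gene \eqn{i} responds.
#'
#' @slot weights numeric N x N matrix of regulatory weights (row = target).
#' @slot bias numeric vector of N basal expression terms.
#' @slot tau numeric vector of N time constants, all strictly positive.
#' @slot deltaT single positive numeric, the simulation time step (default 1).
#'
#' @seealso [RNNetwork()] for the constructor, [simulateExpression()],
#'   [benchmarkNetwork30()].
#' @exportClass RNNetwork
setClass("RNNetwork",
    representation(
        weights = "matrix",
        bias = "numeric",
        tau = "numeric",
        deltaT = "numeric"
    )
)

setValidity("RNNetwork", function(object) {
    w <- object@weights
    n <- nrow(w)
    msg <- character()
    if (ncol(w) != n)
        msg <- c(msg, "'weights' must be a square matrix")
    if (!all(is.finite(w)))
        msg <- c(msg, "'weights' must be finite")
    if (length(object@bias) != n)
        msg <- c(msg, "'bias' must have one entry per gene")
    if (length(object@tau) != n)
        msg <- c(msg, "'tau' must have one entry per gene")
    if (any(!is.finite(object@tau)) || any(object@tau <= 0))
        msg <- c(msg, "all time constants 'tau' must be > 0")
    if (length(object@deltaT) != 1L || !is.finite(object@deltaT) ||
        object@deltaT <= 0)
        msg <- c(msg, "'deltaT' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct an RNNetwork
#'
#' @param weights numeric N x N matrix; entry (i, j) is the effect of gene j
#'   on gene i.
#' @param bias numeric vector of N basal terms (recycled if length 1).
#' @param tau numeric vector of N positive time constants (recycled if
#'   length 1).
#' @param deltaT simulation time step, default 1.
#' @param geneNames optional character vector of N gene labels; defaults to
#'   \code{G1..GN}.
#'
#' @return An [RNNetwork-class] object.
#' @examples
#' net <- RNNetwork(matrix(0, 2, 2), bias = 0, tau = 10)
#' nGenes(net)
#' @export
RNNetwork <- function(weights, bias = 0, tau = 10, deltaT = 1,
                      geneNames = NULL) {
    weights <- as.matrix(weights)
    n <- nrow(weights)
    if (length(bias) == 1L) bias <- rep(bias, n)
    if (length(tau) == 1L) tau <- rep(tau, n)
    if (is.null(geneNames))
        geneNames <- rownames(weights)
    if (is.null(geneNames))
        geneNames <- paste0("G", seq_len(n))
    dimnames(weights) <- list(geneNames, geneNames)
    new("RNNetwork", weights = weights, bias = as.numeric(bias),
        tau = as.numeric(tau), deltaT = as.numeric(deltaT))
}

#' Replicate time-series expression data
#'
#' \code{ExpressionTimeSeries} extends
#' \linkS4class{SummarizedExperiment}: the single \code{expr} assay stores
#' genes in rows and (series, time point) pairs in columns, with the
#' \code{series} and \code{time} columns of \code{colData} recording the
#' replicate series index and the time index within that series. All series
#' share the gene set and the number of time points. Values are expression
#' levels, expected in \eqn{[0, 1]} for model-generated data.
#'
#' @seealso [ExpressionTimeSeries()] for construction from per-series
#'   matrices, [seriesMatrices()], [generateDataset()].
#' @exportClass ExpressionTimeSeries
setClass("ExpressionTimeSeries", contains = "SummarizedExperiment")

setValidity("ExpressionTimeSeries", function(object) {
    cd <- SummarizedExperiment::colData(object)
    msg <- character()
    if (!all(c("series", "time") %in% colnames(cd)))
        return("colData must contain 'series' and 'time' columns")
    a <- SummarizedExperiment::assay(object)
    if (!all(is.finite(a)))
        msg <- c(msg, "expression values must be finite")
    tab <- table(cd$series)
    if (length(unique(tab)) > 1L)
        msg <- c(msg, "all series must have the same number of time points")
    for (s in unique(cd$series)) {
        tt <- sort(cd$time[cd$series == s])
        if (!identical(as.integer(tt), seq_along(tt)))
            msg <- c(msg, sprintf("series %s: time indices must be 1..T", s))
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTimeSeries from per-series matrices
#'
#' @param series a list of M numeric matrices, each T x N with rows = time
#'   points and columns = genes, or a single such matrix.
#' @param geneNames optional character vector of N gene labels; defaults to
#'   the column names of the first series, else \code{G1..GN}.
#'
#' @return An [ExpressionTimeSeries-class] object.
#' @examples
#' mats <- replicate(2, matrix(runif(12), 4, 3), simplify = FALSE)
#' x <- ExpressionTimeSeries(mats)
#' nSeries(x); nTimepoints(x); nGenes(x)
#' @export
ExpressionTimeSeries <- function(series, geneNames = NULL) {
    if (is.matrix(series)) series <- list(series)
    stopifnot(is.list(series), length(series) >= 1L)
    series <- lapply(series, function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "double"
        m
    })
    dims <- vapply(series, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("all series must share the same dimensions (time x genes)")
    nt <- dims[1, 1]
    ng <- dims[2, 1]
    ns <- length(series)
    if (is.null(geneNames)) geneNames <- colnames(series[[1]])
    if (is.null(geneNames)) geneNames <- paste0("G", seq_len(ng))
    expr <- do.call(cbind, lapply(series, t))
    rownames(expr) <- geneNames
    cd <- S4Vectors::DataFrame(
        series = rep(seq_len(ns), each = nt),
        time = rep(seq_len(nt), times = ns)
    )
    colnames(expr) <- sprintf("s%d.t%d", cd$series, cd$time)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = expr), colData = cd)
    new("ExpressionTimeSeries", se)
}

#' Signed gene regulatory network
#'
#' A directed network over N genes stored as an N x N sign matrix: entry
#' (i, j) is +1 if gene j activates gene i, -1 if gene j inhibits gene i and
#' 0 for no regulation. This is both the gold-standard format for the
#' synthetic benchmark and the calling output of network inference.
#'
#' @slot sign numeric N x N matrix with entries in \{-1, 0, +1\}.
#'
#' @seealso [SignedNetwork()], [goldStandard()], [callEdges()],
#'   [confusionMetrics()].
#' @exportClass SignedNetwork
setClass("SignedNetwork", representation(sign = "matrix"))

setValidity("SignedNetwork", function(object) {
    s <- object@sign
    msg <- character()
    if (nrow(s) != ncol(s))
        msg <- c(msg, "'sign' must be a square matrix")
    if (!all(s %in% c(-1, 0, 1)))
        msg <- c(msg, "'sign' entries must be -1, 0 or +1")
    if (length(msg)) msg else TRUE
})

#' Construct a SignedNetwork
#'
#' @param sign square numeric matrix; nonzero entries are reduced to their
#'   sign.
#' @param geneNames optional gene labels for the dimnames.
#' @return A [SignedNetwork-class] object.
#' @examples
#' SignedNetwork(matrix(c(0, -3, 5, 0), 2, 2))
#' @export
SignedNetwork <- function(sign, geneNames = NULL) {
    sign <- sign(as.matrix(sign))
    if (is.null(geneNames)) geneNames <- rownames(sign)
    if (is.null(geneNames)) geneNames <- paste0("G", seq_len(nrow(sign)))
    dimnames(sign) <- list(geneNames, geneNames)
    new("SignedNetwork", sign = sign)
}

#' Result of decoupled RNN network inference
#'
#' Holds the assembled per-gene fits: the N x N fitted weight matrix (zeros
#' outside each gene's selected regulators, so each row has at most
#' \code{iMax} nonzero entries), the fitted bias and time constant of every
#' gene, the per-gene training error reached, the selected regulator sets,
#' and the weight-magnitude threshold used when calling signed edges.
#'
#' @slot weights numeric N x N fitted weight matrix.
#' @slot bias numeric vector of N fitted basal terms.
#' @slot tau numeric vector of N fitted time constants.
#' @slot fitness numeric vector of N per-gene squared-error values.
#' @slot regulators list of N integer vectors of selected regulator indices.
#' @slot stopReason character vector of N per-gene optimizer stop reasons.
#' @slot edgeThreshold single positive numeric used by [callEdges()].
#'
#' @seealso [inferNetwork()], [callEdges()].
#' @exportClass InferredNetwork
setClass("InferredNetwork",
    representation(
        weights = "matrix",
        bias = "numeric",
        tau = "numeric",
        fitness = "numeric",
        regulators = "list",
        stopReason = "character",
        edgeThreshold = "numeric"
    )
)

setValidity("InferredNetwork", function(object) {
    n <- nrow(object@weights)
    msg <- character()
    if (ncol(object@weights) != n)
        msg <- c(msg, "'weights' must be square")
    if (length(object@bias) != n || length(object@tau) != n ||
        length(object@fitness) != n || length(object@regulators) != n)
        msg <- c(msg, "per-gene slots must all have length nrow(weights)")
    if (length(object@edgeThreshold) != 1L || object@edgeThreshold < 0)
        msg <- c(msg, "'edgeThreshold' must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Confusion counts and derived scores for network evaluation
#'
#' Every ordered gene pair (including self-pairs) of a predicted network is
#' classified against the gold standard as TP (both nonzero), TN (both
#' zero), FP (predicted only) or FN (gold only); the four counts always sum
#' to \eqn{N^2}. Derived scores are sensitivity \eqn{TP/(TP+FN)},
#' specificity \eqn{TN/(TN+FP)}, accuracy and the Matthews correlation
#' coefficient.
#'
#' @slot tp,tn,fp,fn integer counts over ordered gene pairs.
#' @slot sensitivity,specificity,accuracy,mcc derived scores.
#'
#' @seealso [confusionMetrics()], [confusionCounts()], [confusionScores()].
#' @exportClass ConfusionMetrics
setClass("ConfusionMetrics",
    representation(
        tp = "integer", tn = "integer", fp = "integer", fn = "integer",
        sensitivity = "numeric", specificity = "numeric",
        accuracy = "numeric", mcc = "numeric"
    )
)
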
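#' Number of genes in an object
#'
#' @param x an [RNNetwork-class], [ExpressionTimeSeries-class],
#'   [SignedNetwork-class] or [InferredNetwork-class] object.
#' @return A single integer.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Gene labels of an object
#'
#' @param x an object with per-gene labels.
#' @return A character vector of gene names.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Number of replicate time series
#'
#' @param x an [ExpressionTimeSeries-class] object.
#' @return A single integer.
#' @export
setGeneric("nSeries", function(x) standardGeneric("nSeries"))

#' Number of time points per series
#'
#' @param x an [ExpressionTimeSeries-class] object.
#' @return A single integer.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Extract replicate series as time x gene matrices
#'
#' @param x an [ExpressionTimeSeries-class] object.
#' @return A list of M numeric matrices, each T x N (rows = time points,
#'   columns = genes).
#' @export
setGeneric("seriesMatrices", function(x) standardGeneric("seriesMatrices"))

#' Regulatory weight matrix
#'
#' @param x an [RNNetwork-class] or [InferredNetwork-class] object.
#' @return The numeric N x N weight matrix (entry (i, j): effect of gene j
#'   on gene i).
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' Basal expression (bias) terms
#'
#' @param x an [RNNetwork-class] or [InferredNetwork-class] object.
#' @return A numeric vector of N bias terms.
#' @export
setGeneric("biasTerms", function(x) standardGeneric("biasTerms"))

#' Gene time constants
#'
#' @param x an [RNNetwork-class] or [InferredNetwork-class] object.
#' @return A numeric vector of N time constants.
#' @export
setGeneric("timeConstants", function(x) standardGeneric("timeConstants"))

#' Sign matrix of a signed network
#'
#' @param x a [SignedNetwork-class] object.
#' @return The numeric N x N matrix with entries in \{-1, 0, +1\}.
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' Number of directed edges of a signed network
#'
#' @param x a [SignedNetwork-class] object.
#' @return A single integer, the number of nonzero entries.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Edge list of a signed network
#'
#' @param x a [SignedNetwork-class] object.
#' @return A data.frame with columns \code{regulator}, \code{target} and
#'   \code{sign} (\code{"+"} or \code{"-"}), 1-based gene indices.
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))
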
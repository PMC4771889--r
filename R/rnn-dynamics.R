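#' Logistic sigmoid activation
#'
#' The squashing function of the RNN gene model, \eqn{f(z) = 1/(1+e^{-z})}.
#' Implemented via [stats::plogis()], which saturates cleanly at extreme
#' arguments instead of overflowing.
#'
#' @param z numeric vector of finite activations.
#' @return Values in (0, 1), strictly increasing in \code{z}.
#' @examples
#' rnnSigmoid(0)       # 0.5
#' rnnSigmoid(c(-800, 800))
#' @export
rnnSigmoid <- function(z) plogis(z)

#' One synchronous update step of the RNN gene model
#'
#' Advances every gene of \code{network} by one time step from the state
#' \code{expression}: gene \eqn{i} moves to
#' \eqn{(\Delta t/\tau_i) f(\sum_j w_{ij} e_j + \beta_i) +
#' (1-\Delta t/\tau_i) e_i}. All genes are updated from the same input row
#' (synchronous update). When all \eqn{\tau_i \ge \Delta t} the new state is
#' a convex combination of a sigmoid output and the previous state, so
#' expression stays in \eqn{[0, 1]}.
#'
#' @param network an [RNNetwork-class] object.
#' @param expression numeric vector of N current expression values.
#' @return Numeric vector of N next-step expression values.
#' @examples
#' net <- RNNetwork(matrix(0, 1, 1), bias = 0, tau = 10)
#' rnnStep(net, 0.5)  # fixed point: 0.1 * 0.5 + 0.9 * 0.5
#' @export
rnnStep <- function(network, expression) {
    stopifnot(is(network, "RNNetwork"))
    expression <- as.numeric(expression)
    if (length(expression) != nGenes(network))
        stop(sprintf("'expression' has length %d but the network has %d genes",
                     length(expression), nGenes(network)))
    if (!all(is.finite(expression)))
        stop("'expression' must be finite")
    a <- network@deltaT / network@tau
    z <- drop(network@weights %*% expression) + network@bias
    unname(a * plogis(z) + (1 - a) * expression)
}

#' Simulate an expression trajectory
#'
#' Iterates [rnnStep()] from an initial state, returning the full trajectory
#' including the initial row.
#'
#' @param network an [RNNetwork-class] object.
#' @param initialExpression numeric vector of N starting values in
#'   \eqn{[0, 1]}.
#' @param nSteps number of update steps to take.
#' @return Numeric matrix of dimension \code{(nSteps + 1) x N}; row 1 is
#'   \code{initialExpression}, row \code{t + 1} the state after \code{t}
#'   steps. Columns carry the gene names.
#' @examples
#' net <- RNNetwork(matrix(0, 1, 1), bias = 0, tau = 10)
#' simulateExpression(net, 0, 3)  # approaches 0.5 geometrically
#' @export
simulateExpression <- function(network, initialExpression, nSteps) {
    stopifnot(is(network, "RNNetwork"))
    initialExpression <- as.numeric(initialExpression)
    if (!all(is.finite(initialExpression)))
        stop("'initialExpression' must be finite")
    if (length(initialExpression) != nGenes(network))
        stop("'initialExpression' must have one value per gene")
    nSteps <- as.integer(nSteps)
    stopifnot(nSteps >= 1L)
    out <- matrix(NA_real_, nSteps + 1L, nGenes(network),
                  dimnames = list(NULL, geneNames(network)))
    out[1L, ] <- initialExpression
    for (t in seq_len(nSteps))
        out[t + 1L, ] <- rnnStep(network, out[t, ])
    out
}
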
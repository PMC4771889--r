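#' @describeIn RNNetwork compact display
#' @param object the object to display.
#' @export
setMethod("show", "RNNetwork", function(object) {
    n <- nGenes(object)
    cat(sprintf("RNNetwork with %d genes, %d regulatory edges\n",
                n, sum(object@weights != 0)))
    cat(sprintf("  deltaT = %g; tau in [%g, %g]; bias in [%g, %g]\n",
                object@deltaT, min(object@tau), max(object@tau),
                min(object@bias), max(object@bias)))
})

#' @describeIn ExpressionTimeSeries compact display
#' @param object the object to display.
#' @export
setMethod("show", "ExpressionTimeSeries", function(object) {
    cat(sprintf(
        "ExpressionTimeSeries: %d genes, %d series x %d time points\n",
        nGenes(object), nSeries(object), nTimepoints(object)))
    a <- SummarizedExperiment::assay(object)
    cat(sprintf("  expression range [%.4g, %.4g]\n", min(a), max(a)))
})

#' @describeIn SignedNetwork compact display
#' @param object the object to display.
#' @export
setMethod("show", "SignedNetwork", function(object) {
    s <- object@sign
    cat(sprintf(
        "SignedNetwork: %d genes, %d edges (%d activating, %d inhibiting)\n",
        nrow(s), sum(s != 0), sum(s > 0), sum(s < 0)))
})

#' @describeIn InferredNetwork compact display
#' @param object the object to display.
#' @export
setMethod("show", "InferredNetwork", function(object) {
    cat(sprintf("InferredNetwork: %d genes, edge threshold %g\n",
                nGenes(object), object@edgeThreshold))
    cat(sprintf("  called edges: %d; per-gene fitness median %.3g (max %.3g)\n",
                edgeCount(callEdges(object)),
                stats::median(object@fitness), max(object@fitness)))
})

#' @describeIn ConfusionMetrics compact display
#' @param object the object to display.
#' @export
setMethod("show", "ConfusionMetrics", function(object) {
    cat(sprintf("ConfusionMetrics: TP=%d TN=%d FP=%d FN=%d\n",
                object@tp, object@tn, object@fp, object@fn))
    cat(sprintf("  Sn=%.3f Sp=%.3f Accuracy=%.3f MCC=%.3f\n",
                object@sensitivity, object@specificity,
                object@accuracy, object@mcc))
})
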
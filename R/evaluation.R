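#' Score a predicted network against a gold standard
#'
#' Classifies every ordered gene pair, self-pairs included (so the counts
#' always sum to \eqn{N^2}), by presence/absence of a regulation: TP if
#' both networks have a nonzero entry, FP if only the prediction does, FN
#' if only the gold standard does, TN if neither. Edge existence is scored
#' unsigned; sign fidelity among the true positives is reported separately
#' by [signAgreement()]. Derived scores:
#' \deqn{S_n = \frac{TP}{TP+FN}, \quad S_p = \frac{TN}{TN+FP}, \quad
#'   Accuracy = \frac{TP+TN}{TP+TN+FP+FN},}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' with MCC defined as 0 when its denominator vanishes.
#'
#' @param predicted,gold [SignedNetwork-class] objects of the same size and
#'   gene ordering.
#' @return A [ConfusionMetrics-class] object.
#' @examples
#' net <- benchmarkNetwork30()
#' m <- confusionMetrics(goldStandard(net), goldStandard(net))
#' confusionScores(m)  # all 1
#' @export
confusionMetrics <- function(predicted, gold) {
    stopifnot(is(predicted, "SignedNetwork"), is(gold, "SignedNetwork"))
    if (nGenes(predicted) != nGenes(gold))
        stop("'predicted' and 'gold' must have the same number of genes")
    p <- predicted@sign != 0
    g <- gold@sign != 0
    tp <- sum(p & g)
    tn <- sum(!p & !g)
    fp <- sum(p & !g)
    fn <- sum(!p & g)
    confusionFromCounts(tp, tn, fp, fn)
}

#' Confusion metrics from raw counts
#'
#' Computes the derived scores from already-tabulated TP/TN/FP/FN counts;
#' the count-level backend of [confusionMetrics()].
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return A [ConfusionMetrics-class] object.
#' @examples
#' confusionFromCounts(32, 860, 4, 4)
#' @export
confusionFromCounts <- function(tp, tn, fp, fn) {
    stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
    total <- tp + tn + fp + fn
    sn <- if (tp + fn > 0) tp / (tp + fn) else NaN
    sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
    acc <- if (total > 0) (tp + tn) / total else NaN
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
    new("ConfusionMetrics",
        tp = as.integer(tp), tn = as.integer(tn),
        fp = as.integer(fp), fn = as.integer(fn),
        sensitivity = sn, specificity = sp, accuracy = acc, mcc = mcc)
}

#' Sign fidelity among true-positive edges
#'
#' Among the ordered pairs where both the prediction and the gold standard
#' have an edge, counts how many agree in sign (same regulation type) and
#' how many are flipped (activation called inhibition or vice versa).
#' Small perturbations of fitted weights are immaterial as long as they do
#' not change the polarity, so this is the natural companion to the
#' unsigned existence scoring of [confusionMetrics()].
#'
#' @param predicted,gold [SignedNetwork-class] objects of the same size.
#' @return A named integer vector \code{c(correct = ..., flipped = ...)}.
#' @export
signAgreement <- function(predicted, gold) {
    stopifnot(is(predicted, "SignedNetwork"), is(gold, "SignedNetwork"))
    if (nGenes(predicted) != nGenes(gold))
        stop("'predicted' and 'gold' must have the same number of genes")
    both <- predicted@sign != 0 & gold@sign != 0
    c(correct = sum(both & predicted@sign == gold@sign),
      flipped = sum(both & predicted@sign != gold@sign))
}

#' Flat evaluation report
#'
#' Collects counts, derived scores (3-decimal display, full precision in
#' the returned values) and sign agreement into a single list, optionally
#' writing it as JSON.
#'
#' @param predicted,gold [SignedNetwork-class] objects.
#' @param file optional path; if given, the report is written as JSON
#'   (requires the \pkg{jsonlite} package).
#' @return (Invisibly, if written) a named list with \code{counts},
#'   \code{scores} and \code{signAgreement}.
#' @export
evaluationReport <- function(predicted, gold, file = NULL) {
    m <- confusionMetrics(predicted, gold)
    rep <- list(counts = as.list(confusionCounts(m)),
                scores = as.list(confusionScores(m)),
                signAgreement = as.list(signAgreement(predicted, gold)))
    if (!is.null(file)) {
        if (!requireNamespace("jsonlite", quietly = TRUE))
            stop("writing a JSON report requires the 'jsonlite' package")
        jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
        return(invisible(rep))
    }
    rep
}
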
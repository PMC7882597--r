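#' Metric suite from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Acc = (TP+TN)/total`, strength `Str = (Sn+Sp)/2` and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator is zero is reported as 0.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts
#' @param auc optional area under the ROC curve to carry in the report
#' @return a [MetricsReport]; rates are proportions, see
#'   [metricsTable()] for the percent view
#' @examples
#' computeMetrics(104, 234, 26, 26)  # Sn 80%, Sp 90%, Acc 86.7%, MCC 0.70
#' @export
computeMetrics <- function(tp, tn, fp, fn, auc = NA_real_) {
    cnt <- c(tp, tn, fp, fn)
    if (any(!is.finite(cnt)) || any(cnt < 0))
        stop("confusion counts must be nonnegative")
    total <- tp + tn + fp + fn
    if (total <= 0) stop("at least one evaluated sample is required")
    sn <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    new("MetricsReport", tp = tp, tn = tn, fp = fp, fn = fn,
        sn = sn, sp = sp, acc = (tp + tn) / total, str = (sn + sp) / 2,
        mcc = mcc, auc = auc)
}

#' Metrics from labels and scores
#'
#' @param yTrue 0/1 truth vector
#' @param scores probabilities in \[0, 1\]
#' @param threshold decision threshold (default 0.5; boundary positive)
#' @param auc compute the ROC AUC as well (default `TRUE`; needs both
#'   classes)
#' @return a [MetricsReport]
#' @export
metricsFromScores <- function(yTrue, scores, threshold = 0.5, auc = TRUE) {
    yTrue <- as.integer(yTrue)
    pred <- classifyScores(scores, threshold)
    computeMetrics(tp = sum(pred == 1L & yTrue == 1L),
                   tn = sum(pred == 0L & yTrue == 0L),
                   fp = sum(pred == 1L & yTrue == 0L),
                   fn = sum(pred == 0L & yTrue == 1L),
                   auc = if (auc && length(unique(yTrue)) == 2L)
                             rocAuc(yTrue, scores) else NA_real_)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midranks for ties: the
#' probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param y 0/1 truth vector with both classes present
#' @param scores numeric scores
#' @return AUC in \[0, 1\]
#' @export
rocAuc <- function(y, scores) {
    y <- as.integer(y)
    n1 <- sum(y == 1L)
    n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute the AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates swept over all score thresholds, suitable
#' for plotting or CSV export.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns `fpr`, `tpr`, `threshold`
#' @export
rocPoints <- function(y, scores) {
    y <- as.integer(y)
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]
    ss <- scores[ord]
    tp <- cumsum(ys == 1L)
    fp <- cumsum(ys == 0L)
    keep <- c(diff(ss) != 0, TRUE)  # one point per distinct threshold
    data.frame(fpr = c(0, fp[keep] / sum(y == 0L)),
               tpr = c(0, tp[keep] / sum(y == 1L)),
               threshold = c(Inf, ss[keep]))
}

#' Percent-scale view of a metrics report
#'
#' @param metrics a [MetricsReport]
#' @return one-row data.frame with `Sn`, `Sp`, `Acc`, `Str` in percent
#'   and `MCC`, `AUC` on their natural scales
#' @export
metricsTable <- function(metrics) {
    stopifnot(is(metrics, "MetricsReport"))
    data.frame(Sn = 100 * metrics@sn, Sp = 100 * metrics@sp,
               Acc = 100 * metrics@acc, Str = 100 * metrics@str,
               MCC = metrics@mcc, AUC = metrics@auc)
}

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf(
        "MetricsReport: Sn %.1f%%  Sp %.1f%%  Acc %.1f%%  Str %.1f%%  MCC %.2f",
        100 * object@sn, 100 * object@sp, 100 * object@acc,
        100 * object@str, object@mcc))
    if (!is.na(object@auc)) cat(sprintf("  AUC %.3f", object@auc))
    cat(sprintf("\n  (TP %d, TN %d, FP %d, FN %d)\n",
                as.integer(object@tp), as.integer(object@tn),
                as.integer(object@fp), as.integer(object@fn)))
})
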
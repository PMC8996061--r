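# Segmentation evaluation: confusion matrices, IoU (per class / micro /
# macro), precision, recall, differences of row-normalised matrices and
# Wilcoxon significance labels for paired score lists.

#' Point-wise confusion matrix
#'
#' \code{counts[i, j]} is the number of points with true class \code{i}
#' and predicted class \code{j}. A point predicted correctly is a true
#' positive (TP) of its class; otherwise it is a false positive (FP) of the
#' predicted class and a false negative (FN) of the true class.
#'
#' @param trueLabels,predictedLabels equal-length integer vectors of 0-based
#'   labels; the unlabelled sentinel is not allowed here.
#' @param scheme the \code{\linkS4class{ClassScheme}}.
#' @return a \code{\linkS4class{ConfusionMatrix}}.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels,
                            scheme = defaultClassScheme()) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (anyNA(trueLabels) || anyNA(predictedLabels))
    stop("confusion matrix requires fully labelled inputs")
  C <- nClasses(scheme)
  if (any(trueLabels < 0 | trueLabels >= C) ||
      any(predictedLabels < 0 | predictedLabels >= C))
    stop("labels outside 0..C-1")
  counts <- matrix(tabulate(as.integer(trueLabels) * C +
                            as.integer(predictedLabels) + 1L, nbins = C * C),
                   nrow = C, byrow = TRUE,
                   dimnames = list(true = classNames(scheme),
                                   predicted = classNames(scheme)))
  new("ConfusionMatrix", counts = counts, scheme = scheme)
}

tpFpFn <- function(cm) {
  counts <- cm@counts
  tp <- diag(counts)
  list(tp = tp, fp = colSums(counts) - tp, fn = rowSums(counts) - tp)
}

#' Row-normalised percentage view of a confusion matrix
#'
#' Each row (true class) is scaled to sum to 100. Rows with no points are
#' returned as NaN.
#'
#' @param x a \code{\linkS4class{ConfusionMatrix}}.
#' @rdname ConfusionMatrix-class
#' @export
setMethod("normalisedPercent", "ConfusionMatrix", function(x) {
  sweep(x@counts, 1, rowSums(x@counts), "/") * 100
})

#' Segmentation metrics
#'
#' \code{iouPerClass}: \code{IoU_c = TP_c / (TP_c + FP_c + FN_c)}, NaN when
#' the denominator is 0 (class absent from truth and prediction).
#' \code{iouMicro}: \code{sum(TP_c) / sum(TP_c + FP_c + FN_c)} -- the pooled,
#' point-level IoU, dominated by majority classes.
#' \code{iouMacro}: unweighted mean of the defined per-class IoU values --
#' every class counts equally regardless of size. \code{precisionRecall}:
#' \code{P_c = TP_c / (TP_c + FP_c)}, \code{R_c = TP_c / (TP_c + FN_c)}.
#'
#' @param x a \code{\linkS4class{ConfusionMatrix}} (for \code{iouMacro},
#'   alternatively a numeric vector of per-class IoU values).
#' @return named numerics; \code{precisionRecall} a list with elements
#'   \code{precision} and \code{recall}.
#' @name evaluation
NULL

#' @rdname evaluation
#' @export
setMethod("iouPerClass", "ConfusionMatrix", function(x) {
  f <- tpFpFn(x)
  denom <- f$tp + f$fp + f$fn
  iou <- ifelse(denom > 0, f$tp / denom, NaN)
  names(iou) <- classNames(x@scheme)
  iou
})

#' @rdname evaluation
#' @export
setMethod("iouMicro", "ConfusionMatrix", function(x) {
  f <- tpFpFn(x)
  sum(f$tp) / sum(f$tp + f$fp + f$fn)
})

#' @rdname evaluation
#' @export
setMethod("iouMacro", "ConfusionMatrix", function(x) {
  iouMacro(iouPerClass(x))
})

#' @rdname evaluation
#' @export
setMethod("iouMacro", "numeric", function(x) {
  defined <- !is.nan(x) & !is.na(x)
  if (!any(defined)) return(NaN)
  if (!all(defined))
    message("iouMacro: ", sum(!defined),
            " undefined per-class IoU value(s) excluded from the macro mean")
  mean(x[defined])
})

#' @rdname evaluation
#' @export
setMethod("precisionRecall", "ConfusionMatrix", function(x) {
  f <- tpFpFn(x)
  P <- ifelse(f$tp + f$fp > 0, f$tp / (f$tp + f$fp), NaN)
  R <- ifelse(f$tp + f$fn > 0, f$tp / (f$tp + f$fn), NaN)
  names(P) <- names(R) <- classNames(x@scheme)
  list(precision = P, recall = R)
})

#' Difference of two row-normalised confusion matrices
#'
#' Element-wise \code{normalisedPercent(b) - normalisedPercent(a)}, in
#' percentage points: the standard "improvement" view when \code{a} is a
#' reference strategy and \code{b} a proposed one. Both inputs may also be
#' plain matrices that are already row-normalised percentages.
#'
#' @param a,b two \code{\linkS4class{ConfusionMatrix}} objects sharing a
#'   scheme, or two equally sized percentage matrices.
#' @return C x C numeric matrix of percentage-point differences; each row
#'   sums to 0 (up to the rounding of the inputs).
#' @rdname diffNormalised
#' @export
setMethod("diffNormalised", signature("ConfusionMatrix", "ConfusionMatrix"),
  function(a, b) {
    if (!identical(classNames(a@scheme), classNames(b@scheme)))
      stop("confusion matrices use different class schemes")
    normalisedPercent(b) - normalisedPercent(a)
  })

#' @rdname diffNormalised
#' @export
setMethod("diffNormalised", signature("matrix", "matrix"), function(a, b) {
  if (!identical(dim(a), dim(b))) stop("matrices differ in dimension")
  b - a
})

#' Full metric report for one segmented cloud
#'
#' Convenience wrapper computing the confusion matrix and all metrics for a
#' pair of label vectors (typically ground truth vs the merged prediction of
#' a full plant cloud).
#'
#' @param trueLabels,predictedLabels 0-based label vectors.
#' @param scheme the \code{\linkS4class{ClassScheme}}.
#' @return a \code{\linkS4class{MetricReport}}.
#' @export
evaluateSegmentation <- function(trueLabels, predictedLabels,
                                 scheme = defaultClassScheme()) {
  cm <- confusionMatrix(trueLabels, predictedLabels, scheme)
  iou <- iouPerClass(cm)
  pr <- precisionRecall(cm)
  new("MetricReport", iou = iou, precision = pr$precision, recall = pr$recall,
      iouMicro = iouMicro(cm), iouMacro = suppressMessages(iouMacro(iou)),
      nPoints = length(trueLabels), confusion = cm)
}

#' @rdname evaluateSegmentation
#' @param x a \code{MetricReport}.
#' @export
metricTable <- function(x) {
  stopifnot(is(x, "MetricReport"))
  data.frame(class = classNames(x@confusion@scheme),
             IoU = unname(x@iou), P = unname(x@precision),
             R = unname(x@recall), row.names = NULL)
}

#' Wilcoxon signed-rank comparison of paired scores
#'
#' Two-sided Wilcoxon signed-rank test on paired score lists (e.g. per-class
#' IoU over repetitions under two sampling strategies). Zero differences are
#' dropped (signed-rank convention); the null distribution is exact for up
#' to 25 untied non-zero pairs and a normal approximation with continuity
#' correction otherwise. All-zero differences give p = 1. The significance
#' label is "n.s.", "*", "**" or "***" at thresholds 0.05, 0.01 and 0.001.
#'
#' @param scoresA,scoresB equal-length numeric vectors (>= 5 pairs); the
#'   pairing unit (cloud, class, repetition) is the caller's choice.
#' @return list with \code{pValue} and \code{stars}.
#' @examples
#' # ten untied positive differences: exact two-sided p = 2 / 2^10
#' comparePaired(1:10, 1:10 + seq(0.1, 1, by = 0.1))
#' @export
comparePaired <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("paired score lists must have equal length")
  if (length(scoresA) < 5) stop("need at least 5 pairs")
  d <- scoresB - scoresA
  nz <- d[d != 0]
  if (length(nz) == 0) return(list(pValue = 1, stars = "n.s."))
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  p <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                           correct = TRUE))$p.value
  list(pValue = p, stars = significanceStars(p))
}

#' @rdname comparePaired
#' @param p a p-value.
#' @export
significanceStars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}
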
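#' @include AllClasses.R
NULL

# MCC with the 0-on-degenerate-denominator convention used for
# per-epoch curves (a constant classifier has no correlation)
.mccSafe <- function(tp, fp, tn, fn) {
  den <- sqrt(as.numeric(tp + fp) * as.numeric(tp + fn) *
                as.numeric(tn + fp) * as.numeric(tn + fn))
  if (den == 0) return(0)
  # the exact value lies in [-1, 1]; guard the sqrt rounding
  max(-1, min(1, (as.numeric(tp) * tn - as.numeric(fp) * fn) / den))
}

#' Confusion counts from labels and predictions
#'
#' Malignant is the positive class: TP counts malignant tiles called
#' malignant, TN benign tiles called benign.
#'
#' @param labels true labels (factor or character, benign / malignant).
#' @param predictions predicted labels, same length.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(labels, predictions) {
  labels <- factor(as.character(labels), levels = c("benign", "malignant"))
  predictions <- factor(as.character(predictions),
                        levels = c("benign", "malignant"))
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  if (anyNA(labels) || anyNA(predictions))
    stop("labels must be 'benign' or 'malignant'")
  pos <- labels == "malignant"
  ppos <- predictions == "malignant"
  new("ConfusionCounts",
      tp = sum(pos & ppos), fp = sum(!pos & ppos),
      tn = sum(!pos & !ppos), fn = sum(pos & !ppos))
}

#' Full metric report from confusion counts
#'
#' Computes the class-conditional rate vocabulary (all in percent,
#' malignant positive): sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), their complements the FN and FP rates, accuracy,
#' precision = TP / (TP + FP), recall (= sensitivity), F-measure =
#' 2 P R / (P + R), and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Requires at least one actual positive and one actual negative.
#' When no tile is predicted positive (TP + FP = 0), precision is
#' undefined; it is reported as 0 with \code{precisionUndefined = TRUE}
#' and a warning.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricReport-class].
#' @examples
#' cc <- new("ConfusionCounts", tp = 91L, fn = 9L, tn = 86L, fp = 14L)
#' metricReport(cc)
#' @export
metricReport <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  if (tp + fn == 0L) stop("no actual positives: sensitivity undefined")
  if (tn + fp == 0L) stop("no actual negatives: specificity undefined")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  precUndef <- (tp + fp) == 0L
  prec <- if (precUndef) {
    warning("no positive predictions; precision reported as 0")
    0
  } else 100 * tp / (tp + fp)
  f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  new("MetricReport",
      sensitivity = sens, specificity = spec,
      fpRate = 100 - spec, fnRate = 100 - sens,
      accuracy = acc, precision = prec, recall = sens, fMeasure = f,
      mcc = .mccSafe(tp, fp, tn, fn), precisionUndefined = precUndef)
}
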
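#' Confusion counts at a decision threshold
#'
#' Scores at or above the threshold are predicted positive (nucleosome);
#' the tie at exactly the threshold counts as positive.
#'
#' @param scores Numeric vector of classifier scores in \[0, 1\].
#' @param labels Binary vector (1 = nucleosome, 0 = linker), same length.
#' @param threshold Decision threshold, default 0.5.
#' @return An object of class `nucnet_confusion`: named integer vector with
#'   elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stopf("empty input")
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stopf("labels must be binary and scores non-missing")
  }
  pred <- as.integer(scores >= threshold)
  out <- c(TP = sum(pred == 1L & labels == 1L),
           FP = sum(pred == 1L & labels == 0L),
           TN = sum(pred == 0L & labels == 0L),
           FN = sum(pred == 0L & labels == 1L))
  structure(out, class = "nucnet_confusion")
}

#' @export
print.nucnet_confusion <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

check_counts <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  if (sum(counts) == 0) stopf("confusion counts are all zero")
  counts
}

#' Classification metrics from confusion counts
#'
#' Standard binary-classification summaries with the nucleosome class as
#' positive: accuracy (TP+TN)/(TP+FP+TN+FN), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), and Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP)).
#'
#' `specificity()` also offers `formula = "tn_fn"` computing TN/(TN+FN)
#' (the negative predictive value), provided for compatibility with reports
#' that print the specificity formula that way.
#'
#' When any factor of the MCC denominator is zero, `mcc()` returns 0 with a
#' warning (the conventional value for a degenerate confusion table).
#'
#' @param counts A `nucnet_confusion` (or named vector with TP/FP/TN/FN).
#' @param formula For `specificity()`: `"standard"` (TN/(TN+FP)) or
#'   `"tn_fn"` (TN/(TN+FN)).
#' @return A single numeric value.
#' @name classification_metrics
NULL

#' @rdname classification_metrics
#' @export
accuracy <- function(counts) {
  counts <- check_counts(counts)
  unname((counts["TP"] + counts["TN"]) / sum(counts))
}

#' @rdname classification_metrics
#' @export
sensitivity <- function(counts) {
  counts <- check_counts(counts)
  unname(counts["TP"] / (counts["TP"] + counts["FN"]))
}

#' @rdname classification_metrics
#' @export
specificity <- function(counts, formula = c("standard", "tn_fn")) {
  counts <- check_counts(counts)
  formula <- match.arg(formula)
  denom <- if (formula == "standard") counts["TN"] + counts["FP"]
           else counts["TN"] + counts["FN"]
  unname(counts["TN"] / denom)
}

#' @rdname classification_metrics
#' @export
mcc <- function(counts) {
  counts <- check_counts(counts)
  tp <- as.numeric(counts["TP"]); fp <- as.numeric(counts["FP"])
  tn <- as.numeric(counts["TN"]); fn <- as.numeric(counts["FN"])
  factors <- c(tn + fn, tn + fp, tp + fn, tp + fp)
  if (any(factors == 0)) {
    warning("MCC denominator has a zero factor; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(factors))
}

#' ROC curve and area under the curve
#'
#' Sweeps all distinct scores as thresholds, computes (FPR, TPR) points and
#' integrates by the trapezoidal rule. The resulting AUC equals the pairwise
#' concordance probability P(score+ > score-) + 0.5 * P(tie).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive); both classes must be present.
#' @return A list with `auc` (numeric) and `curve` (data frame with columns
#'   `fpr`, `tpr`, from (0,0) to (1,1)).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("AUC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores so each distinct threshold contributes one point
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1L - y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

# all five report metrics from scores + labels
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  c(acc = accuracy(cm), sens = sensitivity(cm), spec = specificity(cm),
    mcc = suppressWarnings(mcc(cm)), auc = roc_auc(scores, labels)$auc)
}
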
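# Evaluation metrics for binary activity classification.  Confusion-count
# metrics are computed directly from their defining ratios (they are part of
# the package contract and are identity-tested against the counts); ROC AUC
# is delegated to pROC; average precision is the step-sum over the ranked
# positives.

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- !(y %in% c("active", "inactive"))
    if (any(bad)) stop("labels must be 'active'/'inactive'")
    return(as.integer(y == "active"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(y)
}

#' Classification metrics from predictions
#'
#' Computes the confusion counts and derived rates; when `scores` are given
#' and both classes are present, also the ROC curve / AUC and the
#' precision-recall curve / average precision.
#'
#' @param y_true true labels (`"active"`/`"inactive"`, logical, or 0/1).
#' @param y_pred predicted labels (same encodings).
#' @param scores optional numeric scores (higher = more active) for the
#'   threshold curves.
#' @return An `eval_metrics` list: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `accuracy`, `fpr`, `roc_auc`, `average_precision`, and (with
#'   scores) `roc_curve` / `pr_curve` data.frames of threshold-ordered
#'   points.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  yt <- as_binary_label(y_true)
  yp <- as_binary_label(y_pred)
  stopifnot(length(yt) == length(yp))
  tp <- sum(yt == 1 & yp == 1)
  fp <- sum(yt == 0 & yp == 1)
  tn <- sum(yt == 0 & yp == 0)
  fn <- sum(yt == 1 & yp == 0)
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / length(yt),
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    roc_auc = NA_real_, average_precision = NA_real_)
  if (!is.null(scores) && length(unique(yt)) == 2) {
    out$roc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = yt, predictor = as.numeric(scores),
      levels = c(0, 1), direction = "<", quiet = TRUE)))
    r <- pROC::roc(response = yt, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    out$roc_curve <- data.frame(threshold = r$thresholds,
                                fpr = 1 - r$specificities,
                                tpr = r$sensitivities)
    out$pr_curve <- pr_curve_points(yt, as.numeric(scores))
    out$average_precision <- average_precision(yt, as.numeric(scores))
  }
  class(out) <- "eval_metrics"
  out
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("precision %.4f  recall %.4f  accuracy %.4f  fpr %.4f\n",
              x$precision, x$recall, x$accuracy, x$fpr))
  if (!is.na(x$roc_auc))
    cat(sprintf("roc_auc %.4f  average_precision %.4f\n",
                x$roc_auc, x$average_precision))
  invisible(x)
}

# precision-recall points at every distinct score threshold, best first
pr_curve_points <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # last point per threshold
  data.frame(threshold = s[keep],
             precision = tp[keep] / (tp[keep] + fp[keep]),
             recall = tp[keep] / sum(y))
}

# AP = sum over thresholds of (recall step) * precision, as in the usual
# interpolation-free definition
average_precision <- function(y, s) {
  pc <- pr_curve_points(y, s)
  rec <- c(0, pc$recall)
  sum(diff(rec) * pc$precision)
}
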
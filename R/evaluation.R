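# Binary-classification metrics: confusion counts, accuracy / precision /
# recall / F-measure / MCC, ROC points and trapezoidal AUC.
#
# Metrics with a zero denominator are reported as NA with a reason rather
# than coerced to 0, so fold averages are not silently distorted.

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred Equal-length 0/1 vectors (positive class = 1,
#'   interface).
#' @return A `confusion_counts` list: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " labels vs ",
         length(y_pred), " predictions")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Recall = TP/(TP+FN); Precision = TP/(TP+FP);
#' Accuracy = (TP+TN)/total; F = 2*Pre*Rec/(Pre+Rec);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' @param cc A `confusion_counts` list.
#' @return List `rec`, `pre`, `acc`, `f`, `mcc` plus a character vector
#'   `undefined` naming any metric whose denominator was zero (value `NA`).
#' @export
classification_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  rec <- safe_div(tp, tp + fn, "rec")
  pre <- safe_div(tp, tp + fp, "pre")
  acc <- (tp + tn) / total
  f <- if (is.na(rec) || is.na(pre) || (pre + rec) == 0) {
    undefined <- c(undefined, "f")
    NA_real_
  } else 2 * pre * rec / (pre + rec)
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) {
    undefined <- c(undefined, "mcc")
    NA_real_
  } else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  list(rec = rec, pre = pre, acc = acc, f = f, mcc = mcc,
       undefined = undefined)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the unique score values with the
#' strict rule "positive when score > threshold" (matching the vote
#' tie-break), anchored at (0,0) and (1,1).
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores Finite numeric scores (higher = more positive).
#' @return Data frame `fpr`, `tpr`, `threshold`, sorted for plotting; both
#'   coordinates are monotone non-decreasing.
#' @export
roc_points <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(is.finite(scores)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0) stop("ROC undefined: no positive samples")
  if (n_neg == 0) stop("ROC undefined: no negative samples")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores > t & y_true == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & y_true == 0) / n_neg,
                numeric(1))
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  # drop duplicated consecutive points (e.g. the top threshold repeats (0,0))
  keep <- c(TRUE, diff(out$fpr) > 0 | diff(out$tpr) > 0)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve (trapezoidal)
#'
#' Equals the Mann-Whitney concordance probability (ties counted half).
#'
#' @param roc Data frame from [roc_points()], sorted by `fpr`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  fpr <- roc$fpr
  tpr <- roc$tpr
  if (is.unsorted(fpr)) stop("ROC points must be sorted by FPR")
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Labels + scores straight to a metrics report
#'
#' @param y_true 0/1 labels.
#' @param scores Classifier scores.
#' @param labels Optional hard 0/1 predictions; default `scores > 0.5`.
#' @return List with `confusion`, the five metrics, `roc`, `auc`.
#' @export
metrics_report <- function(y_true, scores, labels = NULL) {
  if (is.null(labels)) labels <- as.integer(scores > 0.5)
  cc <- confusion(y_true, labels)
  roc <- roc_points(y_true, scores)
  c(list(confusion = cc), classification_metrics(cc),
    list(roc = roc, auc = auc(roc)))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
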
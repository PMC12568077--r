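#' Confusion matrix
#'
#' Exact label-pair tally with rows = true labels, columns = predicted.
#'
#' @param true_labels,pred_labels Equal-length vectors.
#' @param levels Optional class ordering (default: sorted union).
#' @return A `confusion_matrix`: integer K x K matrix with dimnames.
#' @export
confusion <- function(true_labels, pred_labels, levels = NULL) {
  if (length(true_labels) != length(pred_labels)) {
    stop("true and predicted label vectors differ in length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(c(true_labels, pred_labels)))
  m <- table(factor(true_labels, levels = levels),
             factor(pred_labels, levels = levels))
  m <- unclass(m)
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

# TP/TN/FP/FN for one positive class of a confusion matrix
binary_counts <- function(cm, positive_class) {
  if (!positive_class %in% rownames(cm)) {
    stop("positive class not in confusion matrix: ", positive_class,
         call. = FALSE)
  }
  i <- match(positive_class, rownames(cm))
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2TP/(2TP+FP+FN)` one-vs-rest for the given positive
#' class. Ratios with zero denominator are reported as `NaN` with a warning.
#' Optional Wilson score intervals are attached for accuracy, precision and
#' recall.
#'
#' @param cm A [confusion()] matrix.
#' @param positive_class The class treated as positive.
#' @param wilson Attach 95% Wilson intervals?
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `n`, `counts`, and optionally `wilson`.
#' @export
classification_metrics <- function(cm, positive_class, wilson = FALSE) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  ct <- binary_counts(cm, positive_class)
  tp <- ct["TP"]; tn <- ct["TN"]; fp <- ct["FP"]; fn <- ct["FN"]
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "F1")
  out <- list(accuracy = unname(acc), precision = unname(prec),
              recall = unname(rec), f1 = unname(f1),
              n = unname(sum(cm)), counts = ct)
  if (wilson) {
    out$wilson <- list(
      accuracy = wilson_interval(unname(tp + tn), sum(cm)),
      precision = if (tp + fp > 0) wilson_interval(unname(tp), unname(tp + fp))
                  else c(NaN, NaN),
      recall = if (tp + fn > 0) wilson_interval(unname(tp), unname(tp + fn))
               else c(NaN, NaN))
  }
  structure(out, class = "metrics_report")
}

#' F1 from a precision/recall pair
#'
#' Harmonic mean `2PR/(P+R)`, the form the evaluation tables print.
#'
#' @param precision,recall Numbers in `[0, 1]`.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(NaN)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.nan(v), "NaN", sprintf("%.2f", v))
  cat(sprintf("<metrics_report> n=%d  acc %s  prec %s  rec %s  F1 %s\n",
              x$n, fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
              fmt(x$f1)))
  if (!is.null(x$wilson)) {
    w <- x$wilson
    cat(sprintf("  95%% CI: acc (%.2f, %.2f)  prec (%.2f, %.2f)  rec (%.2f, %.2f)\n",
                w$accuracy[1], w$accuracy[2], w$precision[1], w$precision[2],
                w$recall[1], w$recall[2]))
  }
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided symmetric-z Wilson score interval. Has better small-sample and
#' boundary coverage than the normal approximation, and never leaves
#' `[0, 1]`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param confidence Confidence level (default 0.95).
#' @return Numeric `(lo, hi)`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Per-sample evaluation of a predicted gait mask against truth
#'
#' Restricts both masks to the valid (labeled) samples and computes binary
#' classification metrics with walking as the positive class.
#'
#' @param truth,pred [gait_mask()]s of equal length.
#' @param valid Logical vector marking evaluable samples (default: all).
#' @param wilson Attach Wilson intervals?
#' @return A `metrics_report`.
#' @export
mask_report <- function(truth, pred, valid = NULL, wilson = FALSE) {
  tv <- truth$is_walking
  pv <- pred$is_walking
  if (length(tv) != length(pv)) {
    stop("masks differ in length", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, length(tv))
  if (!any(valid)) stop("no valid samples to evaluate", call. = FALSE)
  cm <- confusion(ifelse(tv[valid], "walking", "not_walking"),
                  ifelse(pv[valid], "walking", "not_walking"),
                  levels = c("not_walking", "walking"))
  classification_metrics(cm, "walking", wilson = wilson)
}

#' Per-class one-vs-rest metrics table
#'
#' Computes [classification_metrics()] for every class of a multiclass
#' confusion matrix, mirroring the per-activity evaluation-table layout
#' (class, support, accuracy, precision, recall, F1, Wilson CI bounds).
#' Accuracy here is per-class recall on that class's windows, as reported in
#' per-activity tables; precision is one-vs-rest.
#'
#' @param cm A [confusion()] matrix.
#' @param wilson Attach Wilson intervals?
#' @return A named list of `metrics_report`s, one per class.
#' @export
per_class_metrics <- function(cm, wilson = TRUE) {
  out <- lapply(rownames(cm), function(cl) {
    r <- classification_metrics(cm, cl, wilson = wilson)
    r$n <- unname(sum(cm[cl, ]))  # support of the true class
    r
  })
  names(out) <- rownames(cm)
  out
}

#' Median-across-participants aggregation of metric reports
#'
#' Test-set tables report the median performance across participants; this
#' collapses a list of per-participant `metrics_report`s into one report of
#' medians (no intervals).
#'
#' @param reports List of `metrics_report`s.
#' @return A `metrics_report` of medianed metrics.
#' @export
median_report <- function(reports) {
  med <- function(f) stats::median(vapply(reports, `[[`, numeric(1), f),
                                   na.rm = TRUE)
  structure(list(accuracy = med("accuracy"), precision = med("precision"),
                 recall = med("recall"), f1 = med("f1"),
                 n = sum(vapply(reports, `[[`, numeric(1), "n"))),
            class = "metrics_report")
}
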
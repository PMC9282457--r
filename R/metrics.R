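#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (length(y) != length(probabilities)) {
    stop("probabilities and labels differ in length", call. = FALSE)
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' Predicts positive when `probability >= thr` (inclusive boundary).
#'
#' @inheritParams roc_auc
#' @param thr Threshold in \[0, 1\].
#' @return A `confusion_counts` object: named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_at_threshold <- function(probabilities, labels, thr) {
  y <- as.integer(labels)
  pred <- probabilities >= thr
  structure(list(tp = sum(pred & y == 1), tn = sum(!pred & y == 0),
                 fp = sum(pred & y == 0), fn = sum(!pred & y == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$tp, "TN", x$tn, "FP", x$fp, "FN", x$fn, "\n")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the value
#' defined as 0 when any factor of the denominator is 0 (the usual
#' convention, which keeps threshold sweeps total).
#'
#' @param confusion A `confusion_counts` object, or TP with `tn`, `fp`,
#'   `fn` given separately.
#' @param tn,fp,fn Counts when `confusion` is given as the TP count.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(confusion, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(confusion, "confusion_counts")) {
    tp <- confusion$tp; tn <- confusion$tn
    fp <- confusion$fp; fn <- confusion$fn
  } else {
    tp <- confusion
  }
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  if (any(c(tp, tn, fp, fn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Metric panel at the MCC-maximizing threshold
#'
#' Sweeps all decision thresholds that can change the confusion matrix —
#' midpoints between consecutive sorted unique probabilities, plus 0 and 1 —
#' and reports AUC, the MCC-maximizing threshold (ties broken toward the
#' smallest threshold) and the confusion-derived metrics there.
#'
#' @inheritParams roc_auc
#' @return A `metrics_report`: list with `auc`, `threshold`, `confusion`,
#'   `sensitivity`, `specificity`, `mcc`, `n`.
#' @export
best_mcc_threshold <- function(probabilities, labels) {
  y <- as.integer(labels)
  auc <- roc_auc(probabilities, y)  # also validates both classes present
  u <- sort(unique(probabilities))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  best <- -Inf
  best_thr <- cand[1]
  for (thr in cand) {
    m <- mcc(confusion_at_threshold(probabilities, y, thr))
    if (m > best + 1e-12) {
      best <- m
      best_thr <- thr
    }
  }
  conf <- confusion_at_threshold(probabilities, y, best_thr)
  metrics_report(auc, best_thr, conf)
}

#' Assemble a metrics report from an AUC, threshold and confusion counts
#'
#' @param auc Area under the ROC curve.
#' @param threshold Decision threshold used for the confusion counts.
#' @param confusion A `confusion_counts` object.
#' @return A `metrics_report` object.
#' @export
metrics_report <- function(auc, threshold, confusion) {
  sens <- with(confusion, if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  spec <- with(confusion, if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  structure(list(auc = auc, threshold = threshold, confusion = confusion,
                 sensitivity = sens, specificity = spec,
                 mcc = mcc(confusion),
                 n = with(confusion, tp + tn + fp + fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  cat(sprintf("  AUC %.3f | threshold %.4f | MCC %.3f\n",
              x$auc, x$threshold, x$mcc))
  cat(sprintf("  Sensitivity %.3f | Specificity %.3f | TP %d TN %d FP %d FN %d\n",
              x$sensitivity, x$specificity, x$confusion$tp, x$confusion$tn,
              x$confusion$fp, x$confusion$fn))
  invisible(x)
}

#' Flatten metric reports into the standard evaluation table
#'
#' One row per report, mirroring the published evaluation layout: input,
#' feature count, look-ahead range, patient/day counts, the confusion
#' quadruple, AUC, sensitivity, specificity, MCC (rounded to 3 decimals at
#' reporting only).
#'
#' @param reports Named list of `metrics_report` objects.
#' @param info Data frame with one row per report: columns `input`,
#'   `n_features`, `look_ahead`, `n_patients`, `n_days` (recycled if 1 row).
#' @return A data.frame ready for `write.csv`.
#' @export
metrics_table <- function(reports, info) {
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    inf <- info[min(i, nrow(info)), , drop = FALSE]
    data.frame(
      input = inf$input, n_features = inf$n_features,
      look_ahead = inf$look_ahead, n_patients = inf$n_patients,
      n_days = inf$n_days,
      TP = r$confusion$tp, TN = r$confusion$tn,
      FP = r$confusion$fp, FN = r$confusion$fn,
      AUC = round(r$auc, 3), Sensitivity = round(r$sensitivity, 3),
      Specificity = round(r$specificity, 3), MCC = round(r$mcc, 3)
    )
  })
  do.call(rbind, rows)
}
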
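# Evaluation suite: confusion-table metrics, ROC/AUC with DeLong confidence
# intervals, mask IoU, and seeded bootstrap CIs for proportions. Metrics
# with zero denominators are reported as NA with an `undefined` flag rather
# than silently coerced to 0, so tables on degenerate slides stay honest.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; at least one must be
#'   positive.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(v < 0) || sum(v) < 1)
    sil_data_error("confusion counts must be non-negative with total >= 1")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion-table metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, PPV (precision) `TP/(TP+FP)`, NPV `TN/(TN+FN)`, and
#' F1 `2*recall*precision/(recall+precision)`.
#'
#' @param c a [confusion_counts()], or the TP count when `fp`, `tn`, `fn`
#'   are given.
#' @param fp,tn,fn optional counts when `c` is scalar.
#' @return named list with the six metrics (NA where the denominator is
#'   zero) and `undefined`, the names of undefined metrics.
#' @export
confusion_metrics <- function(c, fp = NULL, tn = NULL, fn = NULL) {
  if (!inherits(c, "confusion_counts")) c <- confusion_counts(c, fp, tn, fn)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(c$TP, c$TP + c$FN)
  spec <- safe_div(c$TN, c$TN + c$FP)
  acc <- safe_div(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN)
  ppv <- safe_div(c$TP, c$TP + c$FP)
  npv <- safe_div(c$TN, c$TN + c$FN)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0)
    2 * sens * ppv / (sens + ppv)
  else NA_real_
  out <- list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    PPV = ppv, NPV = npv, F1 = f1
  )
  out$undefined <- names(out)[vapply(out, function(x) is.na(x[1]), logical(1))]
  out
}

check_scored_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    sil_data_error("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1)))
    sil_data_error("labels must be 0/1")
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    sil_data_error("AUC requires at least one positive and one negative")
}

#' ROC curve and AUC
#'
#' The empirical ROC by threshold sweep over the unique scores, and the AUC
#' as the Mann-Whitney statistic `P(score_pos > score_neg) + 0.5 * P(tie)`
#' (ties get half credit), computed rank-based in O(n log n).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels.
#' @return list with `thresholds`, `TPR`, `FPR` (one point per unique
#'   threshold, plus the extremes) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_scored_labels(scores, labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, 0)
  list(
    thresholds = c(Inf, thr),
    TPR = c(0, tpr),
    FPR = c(0, fpr),
    auc = auc
  )
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the empirical AUC from placement values: the
#' variance of the per-positive placements over the positives plus the
#' variance of the per-negative placements over the negatives, each divided
#' by its class size; the CI is the normal approximation, clipped to
#' `[0, 1]`. The point estimate equals [roc_auc()]'s AUC exactly.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (>= 2 per class).
#' @param alpha 1 - confidence level (default 0.05 for a 95% CI).
#' @return list with `auc`, `lower`, `upper`, `se`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  check_scored_labels(scores, labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m < 2 || n < 2)
    sil_data_error("DeLong CI requires at least 2 scores per class")
  # placement of each positive among negatives, and vice versa
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n, 0)
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m, 0)
  auc <- mean(v10)
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  if (s2 == 0)
    warning("degenerate DeLong variance (perfect separation); zero-width CI")
  se <- sqrt(s2)
  z <- stats::qnorm(1 - alpha / 2)
  list(
    auc = auc,
    lower = max(0, auc - z * se),
    upper = min(1, auc + z * se),
    se = se
  )
}

#' Intersection over union of two masks
#'
#' `|a & b| / |a | b|`. Two empty masks are in perfect agreement; IoU is
#' defined as 1 with a warning.
#'
#' @param a,b binary masks of equal shape.
#' @return fraction in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    sil_data_error("masks must have equal shapes")
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty; IoU defined as 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Bootstrap confidence intervals for confusion-based metrics
#'
#' Percentile bootstrap over case resamples for sensitivity, specificity,
#' accuracy, PPV, NPV and F1 — the CI method used for proportion metrics in
#' the evaluation tables (the AUC uses [delong_ci()] instead). Seeded and
#' deterministic.
#'
#' @param truth 0/1 ground-truth labels per case.
#' @param predicted 0/1 predicted labels per case.
#' @param n_boot number of resamples (default 2000).
#' @param alpha 1 - confidence level.
#' @param seed integer seed.
#' @return data frame with `metric`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_metric_ci <- function(truth, predicted, n_boot = 2000,
                                alpha = 0.05, seed = 1L) {
  if (length(truth) != length(predicted))
    sil_data_error("truth and predicted must have equal length")
  metric_names <- c("sensitivity", "specificity", "accuracy", "PPV", "NPV", "F1")
  point <- unlist(confusion_from_labels(truth, predicted)[metric_names])
  n <- length(truth)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      unlist(confusion_from_labels(truth[idx], predicted[idx])[metric_names])
    }, numeric(length(metric_names)))
  })
  qs <- apply(draws, 1, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  data.frame(
    metric = metric_names,
    estimate = unname(point),
    lower = unname(qs[1, ]),
    upper = unname(qs[2, ]),
    row.names = NULL
  )
}

confusion_from_labels <- function(truth, predicted) {
  confusion_metrics(confusion_counts(
    tp = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fn = sum(truth == 1 & predicted == 0)
  ))
}
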
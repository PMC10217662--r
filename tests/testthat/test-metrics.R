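test_that("confusion metrics reproduce the worked example exactly", {
  m <- confusion_metrics(confusion_counts(tp = 8, fp = 3, tn = 7, fn = 2))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.75)
  expect_equal(round(m$PPV, 4), 0.7273)
  expect_equal(round(m$NPV, 4), 0.7778)
  expect_equal(round(m$F1, 4), 0.7619)
  expect_length(m$undefined, 0)

  perfect <- confusion_metrics(confusion_counts(5, 0, 5, 0))
  for (k in c("sensitivity", "specificity", "accuracy", "PPV", "NPV", "F1"))
    expect_equal(perfect[[k]], 1)

  # no predicted positives: sensitivity 0, PPV and F1 flagged undefined
  deg <- confusion_metrics(confusion_counts(0, 0, 5, 5))
  expect_equal(deg$sensitivity, 0)
  expect_true(all(c("PPV", "F1") %in% deg$undefined))
  expect_true(is.na(deg$PPV))
  expect_error(confusion_counts(0, 0, 0, 0), "total >= 1")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(61)
  for (trial in 1:200) {
    v <- rmultinom(1, 200, c(0.3, 0.2, 0.3, 0.2))[, 1] + 1
    m <- confusion_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    P <- v[1] + v[4]; N <- v[2] + v[3]
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
    vals <- unlist(m[c("sensitivity", "specificity", "accuracy", "PPV", "NPV", "F1")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("AUC equals the pairwise statistic and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  set.seed(62)
  for (trial in 1:30) {
    n <- 50
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    r <- roc_auc(scores, labels)
    expect_lt(abs(r$auc - auc_oracle(scores, labels)), 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    r2 <- roc_auc(exp(3 * scores) + 1, labels)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
  # independence -> AUC ~ 0.5 at large n
  set.seed(63)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), "positive and")
})

test_that("ROC curve sweeps thresholds from none to all", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(r$TPR[1], 0)
  expect_equal(r$FPR[1], 0)
  expect_equal(r$TPR[length(r$TPR)], 1)
  expect_equal(r$FPR[length(r$FPR)], 1)
  expect_true(all(diff(r$TPR) >= 0))
  expect_true(all(diff(r$FPR) >= 0))
})

test_that("AUC and DeLong CI agree with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (trial in 1:10) {
    scores <- c(rnorm(40, 1), rnorm(50))
    labels <- c(rep(1, 40), rep(0, 50))
    ours <- delong_ci(scores, labels)
    ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(ours$lower, max(0, ci[1]), tolerance = 1e-9)
    expect_equal(ours$upper, min(1, ci[3]), tolerance = 1e-9)
  }
})

test_that("DeLong point estimate matches roc_auc and the CI shrinks with n", {
  set.seed(65)
  scores <- c(rnorm(30, 0.8), rnorm(30))
  labels <- rep(c(1, 0), each = 30)
  expect_equal(delong_ci(scores, labels)$auc, roc_auc(scores, labels)$auc)

  expect_warning(
    perfect <- delong_ci(c(10, 11, 1, 2), c(1, 1, 0, 0)),
    "degenerate"
  )
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$lower, 1)

  width <- function(n, seed) {
    set.seed(seed)
    s <- c(rnorm(n, 1.19), rnorm(n))
    l <- rep(c(1, 0), each = n)
    ci <- delong_ci(s, l)
    ci$upper - ci$lower
  }
  expect_gt(width(50, 1), width(5000, 1))
  # ~ 1/sqrt(n) scaling: a factor 100 in n shrinks the width ~ 10x
  expect_equal(width(50, 2) / width(5000, 2), 10, tolerance = 5)
})

test_that("mask IoU handles identity, disjoint and partial overlap", {
  a <- matrix(0L, 10, 10); a[1:5, 1:10] <- 1L
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(0L, 10, 10); b[6:10, 1:10] <- 1L
  expect_equal(mask_iou(a, b), 0)
  # half-overlapping equal rectangles -> 1/3
  c1 <- matrix(0L, 10, 12); c1[, 1:8] <- 1L
  c2 <- matrix(0L, 10, 12); c2[, 5:12] <- 1L
  expect_equal(mask_iou(c1, c2), 1 / 3)
  expect_warning(v <- mask_iou(matrix(0L, 3, 3), matrix(0L, 3, 3)), "empty")
  expect_equal(v, 1)
  expect_error(mask_iou(a, matrix(0L, 3, 3)), "equal shapes")
})

test_that("bootstrap CIs are seeded, ordered and cover the point estimate", {
  set.seed(66)
  truth <- rbinom(120, 1, 0.5)
  pred <- ifelse(runif(120) < 0.85, truth, 1 - truth)
  ci <- bootstrap_metric_ci(truth, pred, n_boot = 200, seed = 3)
  expect_identical(ci, bootstrap_metric_ci(truth, pred, n_boot = 200, seed = 3))
  expect_true(all(ci$lower <= ci$estimate + 1e-9))
  expect_true(all(ci$upper >= ci$estimate - 1e-9))
  expect_equal(ci$metric[1], "sensitivity")
})
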
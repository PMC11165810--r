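test_that("confusion counts follow the >= threshold rule", {
  c1 <- confusion_counts(c(1, 0), c(0.9, 0.1))
  expect_equal(as.numeric(c1), c(1, 0, 0, 1), ignore_attr = TRUE)
  # ties at the threshold are predicted positive
  c2 <- confusion_counts(c(1, 0, 0), c(0.5, 0.5, 0.5))
  expect_equal(c2$fp, 2)
  expect_equal(c2$fn, 0)
  set.seed(1)
  for (rep in 1:5) {
    labels <- rbinom(50, 1, 0.4)
    probs <- runif(50)
    got <- confusion_counts(labels, probs)
    want <- oracle_confusion(labels, probs)
    expect_equal(as.numeric(got), as.numeric(want), ignore_attr = TRUE)
  }
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
  expect_error(confusion_counts(c(1, 2), c(0.5, 0.5)), "binary")
})

test_that("threshold metrics match the closed-form definitions", {
  m <- classification_metrics(tibble::tibble(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  perfect <- classification_metrics(tibble::tibble(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(as.numeric(perfect), rep(1, 4), ignore_attr = TRUE)
  degenerate <- classification_metrics(tibble::tibble(tp = 0, fp = 0, fn = 2, tn = 3))
  expect_equal(degenerate$precision, 0)  # 0 by convention, not NaN
  expect_equal(degenerate$f1, 0)
})

test_that("ROC AUC equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.3)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.8, 0.3)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)   # rounded scores force ties
    expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC AUC agrees with an independent library implementation", {
  set.seed(3)
  for (rep in 1:5) {
    labels <- c(1, 0, rbinom(30, 1, 0.5))
    scores <- runif(32)
    expect_equal(roc_auc(labels, scores),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("PR AUC matches a hand-stepped curve and the sweep oracle", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.3)), 1)
  # 6-point toy stepped by hand: scores descending .9 .8 .7 .6 .5 .4,
  # labels 1 0 1 1 0 0 -> steps at ranks 1 (P=1), 3 (P=2/3), 4 (P=3/4)
  labels <- c(1, 0, 1, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  expect_equal(pr_auc(labels, scores),
               (1 / 3) * 1 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4))
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.4))
    scores <- round(runif(n), 1)
    expect_equal(pr_auc(labels, scores), oracle_aupr(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("random scores give AUPR near the prevalence", {
  set.seed(5)
  labels <- rbinom(4000, 1, 0.3)
  scores <- runif(4000)
  expect_lt(abs(pr_auc(labels, scores) - 0.3), 0.05)
  expect_lt(abs(roc_auc(labels, scores) - 0.5), 0.05)
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(6)
  labels <- c(1, 0, rbinom(40, 1, 0.5))
  scores <- runif(42)
  expect_equal(roc_auc(labels, scores), roc_auc(labels, scores^3))
  expect_equal(pr_auc(labels, scores), pr_auc(labels, scores^3))
})

test_that("curve points use the standard TPR/FPR orientation", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.8, 0.3)
  pts <- roc_points(labels, scores)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  # at threshold 0.9 only the top positive is called: TPR 1/2, FPR 0
  expect_equal(pts$tpr[2], 0.5)
  expect_equal(pts$fpr[2], 0)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("the six-metric report behaves on separable, null and random input", {
  sep <- metric_report(c(1, 1, 1, 0, 0, 0), c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(sep), rep(1, 6), ignore_attr = TRUE)
  set.seed(7)
  null_aucs <- replicate(10, {
    labels <- rbinom(300, 1, 0.5)
    metric_report(sample(labels), runif(300))$auc
  })
  expect_true(mean(null_aucs) > 0.4 && mean(null_aucs) < 0.6)
  r <- metric_report(c(1, 0, rbinom(30, 1, 0.5)), runif(32))
  expect_true(all(as.numeric(r) >= 0 & as.numeric(r) <= 1))
})
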
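# Metric suite: confusion counts, derived metrics with the printed-table
# worked examples, ROC/AUC against the brute-force oracle, NG baseline.

test_that("confusion counts labels correctly", {
  cm <- confusion(c(1, 1, 0), c(1, 0, 0))
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]), c(tp = 1, fn = 1, tn = 1, fp = 0))
  cm2 <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm2$fp + cm2$fn, 0)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics reproduce the blind-test worked examples at 2 decimals", {
  # best structure-based model column: (tp 4, fp 3, tn 73, fn 1)
  f <- format_metrics(metrics(confusion_counts(4, 3, 73, 1)))
  expect_equal(unname(f[c("accuracy", "recall", "specificity", "precision", "mcc")]),
               c("0.95", "0.80", "0.96", "0.57", "0.65"))
  # all-negative predictor column: (0, 0, 76, 5)
  m0 <- metrics(confusion_counts(0, 0, 76, 5))
  expect_equal(m0$recall, 0)
  expect_equal(m0$specificity, 1)
  expect_equal(m0$mcc, 0) # zero-denominator convention
  expect_true(is.na(m0$precision))
  expect_equal(unname(format_metrics(m0)["precision"]), "-")
  # single-true-positive column: (1, 0, 76, 4) -> recall 0.2, precision 1
  m1 <- metrics(confusion_counts(1, 0, 76, 4))
  expect_equal(m1$recall, 0.2)
  expect_equal(m1$precision, 1)
  # sequence-baseline column: (5, 7, 69, 0)
  fng <- format_metrics(metrics(confusion_counts(5, 7, 69, 0)))
  expect_equal(unname(fng[c("recall", "precision", "mcc")]),
               c("1.00", "0.42", "0.62"))
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("MCC is symmetric under class swap and perfect prediction scores 1", {
  set.seed(19)
  for (i in 1:20) {
    truth <- sample(c(0, 1), 30, replace = TRUE)
    pred <- sample(c(0, 1), 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- metrics(confusion(truth, pred))
    mswap <- metrics(confusion(1 - truth, 1 - pred))
    expect_equal(m$mcc, mswap$mcc)
    mid <- metrics(confusion(truth, truth))
    expect_equal(mid$accuracy, 1)
    expect_equal(mid$mcc, 1)
  }
})

test_that("trapezoid AUC equals brute-force concordance on 500 random sets", {
  set.seed(23)
  for (i in seq_len(500)) {
    n <- sample(4:12, 1)
    truth <- c(1, 0, sample(c(0, 1), n - 2, replace = TRUE))
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1)) # force ties often
    got <- roc_auc(truth, scores)
    expect_equal(got$auc, oracle_auc(truth, scores), tolerance = 1e-12)
    # anchors present
    expect_equal(got$roc$fpr[1], 0)
    expect_equal(got$roc$tpr[nrow(got$roc)], 1)
  }
})

test_that("AUC limits and invariances hold", {
  truth <- c(1, 1, 0, 0, 0)
  expect_equal(roc_auc(truth, c(0.9, 0.8, 0.2, 0.1, 0.05))$auc, 1)
  expect_equal(roc_auc(truth, rep(0.5, 5))$auc, 0.5)
  # derived by pair counting: positives {0.9, 0.4} vs negatives {0.5, 0.3, 0.2}
  expect_equal(roc_auc(c(1, 1, 0, 0, 0), c(0.9, 0.4, 0.5, 0.3, 0.2))$auc, 5 / 6)
  set.seed(3)
  scores <- stats::rnorm(20)
  truth2 <- sample(c(0, 1), 20, replace = TRUE, prob = c(0.7, 0.3))
  truth2[1:2] <- c(0, 1)
  a <- roc_auc(truth2, scores)$auc
  expect_equal(roc_auc(truth2, -scores)$auc, 1 - a)
  expect_equal(roc_auc(truth2, exp(scores))$auc, a) # monotone invariance
  expect_error(roc_auc(rep(1, 5), stats::rnorm(5)), "both classes")
})

test_that("NG-motif baseline flags exactly the Asn-Gly sites", {
  sites <- data.frame(yyy = c("G", "S", "G", NA, "T"))
  expect_equal(ng_motif_baseline(sites), c(1L, 0L, 1L, 0L, 0L))
  fix <- build_ng_test_sites()
  bl <- ng_motif_baseline(fix$sites)
  cm <- confusion(fix$truth, bl)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 5, fp = 7, tn = 69, fn = 0))
})
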
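# Metrics: closed-form confusion statistics, Dice, ROC/AUC equivalence
# with the Mann-Whitney statistic, and the Youden cut-point.

test_that("confusion metrics reproduce hand-computed closed forms", {
  perfect <- classification_metrics(confusion_counts(1, 0, 1, 0))
  expect_true(all(perfect == 1))
  m <- classification_metrics(confusion_counts(tp = 8, fp = 2, tn = 9,
                                               fn = 1))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-12)
  expect_equal(m$precision, 0.8)
  expect_equal(m$specificity, 9 / 11, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  # harmonic mean of a reference recall/precision pair
  r <- 0.9485; p <- 0.9985
  expect_equal(round(2 * p * r / (p + r), 4), 0.9729)
  # zero denominators are undefined, not zero
  u <- classification_metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(u$recall) && is.na(u$precision) && is.na(u$f1))
  expect_equal(u$accuracy, 1)
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
  expect_error(confusion_counts(0, 0, 0, 0), "positive total")
})

test_that("F1 lies between precision and recall (harmonic-mean property)", {
  set.seed(41)
  for (i in 1:200) {
    cc <- confusion_counts(sample(1:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    m <- classification_metrics(cc)
    if (any(is.na(c(m$precision, m$recall, m$f1)))) next
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    if (m$precision == m$recall) expect_equal(m$f1, m$precision)
  }
})

test_that("Dice similarity: identity, disjointness, shifted-square case", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dsc(a, b), 0)
  # 10x10 square against itself shifted 5 px: 2*50 / (100+100)
  shifted <- matrix(FALSE, 20, 20); shifted[1:10, 6:15] <- TRUE
  expect_equal(dsc(a, shifted), 0.5)
  expect_equal(dsc(a, shifted), dsc(shifted, a))
  expect_true(is.na(dsc(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))))
  expect_error(dsc(a, matrix(FALSE, 3, 3)), "grid")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-counting statistic", {
  mw <- function(scores, labels) {
    sp <- scores[labels]; sn <- scores[!labels]
    mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(mw(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  # endpoints present
  expect_equal(r$points$sensitivity[1], 0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$sensitivity[nrow(r$points)], 1)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                      FALSE))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties
    expect_equal(roc_auc(scores, labels)$auc, mw(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    labels <- c(TRUE, FALSE, runif(30) < 0.4)
    scores <- runif(32)
    ours <- roc_auc(scores, labels)$auc
    # pin the direction: pROC otherwise flips curves below the diagonal
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("Youden cut-point maximises J with ties toward higher thresholds", {
  # perfect classifier: J = 1 at the boundary between the classes
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  cp <- youden_cutpoint(r)
  expect_equal(as.numeric(cp), 0.8)
  expect_equal(attr(cp, "youden"), 1)
  # all scores equal: J = 0 everywhere, highest (only) threshold returned
  r2 <- roc_auc(rep(0.7, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(youden_cutpoint(r2)), 0.7)
  expect_equal(attr(youden_cutpoint(r2), "youden"), 0)
  # brute-force sweep on a hand-built score set
  scores <- c(0.95, 0.9, 0.8, 0.6, 0.4, 0.2)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r3 <- roc_auc(scores, labels)
  brute <- sapply(sort(unique(scores), decreasing = TRUE), function(t) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    sens + spec - 1
  })
  best_thr <- max(sort(unique(scores),
                       decreasing = TRUE)[brute >= max(brute) - 1e-12])
  expect_equal(as.numeric(youden_cutpoint(r3)), best_thr)
  expect_equal(attr(youden_cutpoint(r3), "youden"), max(brute))
})

test_that("tidy/glance/autoplot interfaces work on ROC curves", {
  r <- roc_auc(c(0.9, 0.7, 0.4, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_s3_class(tidy(r), "tbl_df")
  gl <- glance(r)
  expect_equal(gl$auc, 1)
  expect_equal(gl$youden_cutpoint, 0.7)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("Wilson interval and paired-call comparisons behave sanely", {
  ci <- wilson_ci(90, 100)
  expect_true(ci[1] < 0.9 && ci[2] > 0.9)
  expect_true(ci[1] > 0.8 && ci[2] < 0.96)
  cmp <- compare_paired_calls(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                              c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(cmp$gained, 1L)
  expect_identical(cmp$lost, 0L)
  expect_true(is.finite(cmp$mcnemar_p))
})
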
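test_that("confusion metrics match the standard definitions", {
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), rep(1, 4))
  never <- confusion_metrics(rep(FALSE, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(never$sensitivity, 0)
  expect_equal(never$specificity, 1)
  expect_true(is.na(never$ppv))
  expect_true("ppv" %in% never$undefined)
  expect_error(confusion_metrics(c(TRUE, TRUE), c(TRUE, TRUE)),
               "positive and one negative")
})

test_that("the reconstructed trial table yields the published metric block", {
  ref <- reference_cohort()
  cm <- confusion_metrics(ref$rpa_pred, ref$pcr)
  expect_equal(cm$sensitivity, 11 / 13)   # 84.6% -> rounds to 85
  expect_equal(cm$sensitivity_pct, 85)
  expect_equal(cm$specificity_pct, 92)
  expect_equal(cm$ppv_pct, 92)
  expect_equal(cm$npv_pct, 86)
})

test_that("ordinal AUC equals pair counting, with all-tie scores at 0.5", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(auc_ordinal(rep(2, 5), truth)$auc, 0.5)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    truth <- stats::runif(n) < 0.5
    if (!any(truth) || all(truth)) truth[1] <- !truth[1]
    scores <- sample(1:5, n, replace = TRUE)
    expect_equal(auc_ordinal(scores, truth)$auc,
                 auc_pair_oracle(scores, truth))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(62)
  truth <- stats::runif(30) < 0.4
  truth[1:2] <- c(TRUE, FALSE)
  scores <- stats::rnorm(30)
  a0 <- auc_ordinal(scores, truth)$auc
  expect_equal(auc_ordinal(exp(scores), truth)$auc, a0)
  expect_equal(auc_ordinal(rank(scores), truth)$auc, a0)
})

test_that("a binary predictor's AUC equals (sensitivity + specificity) / 2", {
  set.seed(63)
  for (i in 1:10) {
    truth <- stats::runif(20) < 0.5
    if (!any(truth) || all(truth)) truth[1] <- !truth[1]
    pred <- stats::runif(20) < 0.5
    cm <- confusion_metrics(pred, truth)
    expect_equal(auc_ordinal(as.numeric(pred), truth)$auc,
                 (cm$sensitivity + cm$specificity) / 2)
  }
})

test_that("ordinal group scores on the reference cohort give AUC 155.5/169", {
  ref <- reference_cohort()
  a <- auc_ordinal(ref$rpa_score, ref$pcr)
  expect_equal(a$auc, 155.5 / 169)
  expect_equal(round(a$auc, 2), 0.92)
  # published confidence interval, truncated at 1
  expect_equal(round(a$ci_low, 2), 0.82)
  expect_equal(a$ci_high, 1)
})

test_that("AUC and DeLong variance agree with pROC", {
  set.seed(64)
  truth <- stats::runif(40) < 0.5
  truth[1:2] <- c(TRUE, FALSE)
  s1 <- stats::rnorm(40) + truth
  s2 <- stats::rnorm(40) + 0.5 * truth
  a <- auc_ordinal(s1, truth)
  roc1 <- pROC::roc(truth, s1, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(roc1)))
  expect_equal(as.numeric(pROC::var(roc1)), a$variance, tolerance = 1e-10)
  roc2 <- pROC::roc(truth, s2, quiet = TRUE, direction = "<")
  ours <- delong_paired_test(s1, s2, truth)
  theirs <- pROC::roc.test(roc1, roc2, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
})

test_that("paired DeLong test honours identity and antisymmetry", {
  set.seed(65)
  truth <- stats::runif(26) < 0.5
  truth[1:2] <- c(TRUE, FALSE)
  s1 <- stats::rnorm(26) + truth
  s2 <- stats::rnorm(26)
  same <- delong_paired_test(s1, s1, truth)
  expect_true(same$tie)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  fwd <- delong_paired_test(s1, s2, truth)
  rev <- delong_paired_test(s2, s1, truth)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p_value, rev$p_value)
})

test_that("ROC points trace from (0,0) to (1,1) and respect the AUC", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  scores <- c(3, 3, 2, 2, 1)
  pts <- roc_points(scores, truth)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoidal area under the staircase equals the Mann-Whitney estimate
  area <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  expect_equal(area, auc_ordinal(scores, truth)$auc)
})
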
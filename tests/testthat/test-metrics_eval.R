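test_that("confusion counts match enumeration and label conventions", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))
  y <- c("dead", "live", "dead")
  cm2 <- confusion(y, c("dead", "dead", "dead"))
  expect_equal(cm2$FN, 0); expect_equal(cm2$TN, 0)
  expect_equal(cm2$TP, 2); expect_equal(cm2$FP, 1)
  cm3 <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm3$FP + cm3$FN, 0)
  expect_error(confusion(c(1, 2, 0), c(1, 0, 0)), "binary")
})

test_that("metric formulas match hand arithmetic and identities", {
  cm <- structure(list(TP = 45, FP = 5, FN = 5, TN = 45),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(m$Acc, 0.9); expect_equal(m$TPR, 0.9)
  expect_equal(m$FPR, 0.1); expect_equal(m$PRE, 0.9)
  expect_equal(m$F1, 0.9); expect_equal(m$GM, 0.9)
  expect_equal(m$TPR + m$FPR - m$FPR, m$REC)   # REC is TPR
  expect_equal(m$FPR + m$TNR, 1)
  # Acc = (TPR*P + TNR*N)/(P+N)
  P <- cm$TP + cm$FN; N <- cm$FP + cm$TN
  expect_equal(m$Acc, (m$TPR * P + m$TNR * N) / (P + N))
  # perfect classifier
  mp <- classification_metrics(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unlist(mp[c("Acc", "TPR", "TNR", "PRE", "F1", "GM")]),
               c(Acc = 1, TPR = 1, TNR = 1, PRE = 1, F1 = 1, GM = 1))
  expect_equal(mp$FPR, 0)
  # TP = 0 with predictions present: PRE and F1 are 0
  m0 <- classification_metrics(confusion(c(1, 0), c(0, 1)))
  expect_equal(m0$PRE, 0); expect_equal(m0$F1, 0)
  # undefined denominators yield NA, not 0
  mna <- classification_metrics(confusion(c(1, 1), c(1, 1)))
  expect_true(is.na(mna$FPR))
})

test_that("trapezoidal AUC equals brute-force concordance up to n = 200", {
  set.seed(13)
  for (r in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- if (r %% 3 == 0) sample(5, n, replace = TRUE)  # heavy ties
         else rnorm(n) + y * runif(1, 0, 2)
    expect_equal(roc_auc(y, s)$auc, concordance_auc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("AUC is a rank statistic with the expected extremes and null", {
  y <- c(rep(0, 5), rep(1, 5))
  s <- c(1:5, 6:10)
  expect_equal(roc_auc(y, s)$auc, 1)
  expect_equal(roc_auc(y, exp(s))$auc, 1)          # monotone invariance
  set.seed(17)
  y2 <- rbinom(1e4, 1, 0.5); s2 <- rnorm(1e4)
  expect_equal(roc_auc(y2, s2)$auc, 0.5, tolerance = 0.06)
  expect_equal(roc_auc(y2, 2 * s2 + 7)$auc, roc_auc(y2, s2)$auc)
  expect_error(roc_auc(rep(1, 4), rnorm(4)), "positive and one negative")
  # p-value: separated scores are significant, null scores are not
  expect_lt(auc_pvalue(y, s), 0.05)
})

test_that("ROC endpoints and monotonicity hold", {
  set.seed(19)
  y <- rbinom(50, 1, 0.5); s <- rnorm(50)
  roc <- roc_auc(y, s)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("stratified folds partition 398 records into near-equal folds", {
  co <- generate_cohort(n = 398, seed = 1, exact_counts = TRUE)
  y <- cohort_labels(co)
  fid <- stratified_folds(y, k = 5, seed = 2)
  expect_equal(sort(unique(fid)), 1:5)
  sizes <- as.integer(table(fid))
  expect_equal(sum(sizes), 398)
  expect_lte(max(sizes) - min(sizes), 1)
  # both classes present in every fold, proportions preserved
  for (f in 1:5) {
    expect_gte(sum(y[fid == f] == 1), 1)
    expect_gte(sum(y[fid == f] == 0), 1)
  }
  expect_identical(stratified_folds(y, 5, seed = 2), fid)
  expect_error(stratified_folds(c(1, rep(0, 20)), k = 5), "too rare")
})

test_that("cross-validation with a constant classifier yields the majority share", {
  # all-zero features force a constant score; MSE training pushes that
  # constant towards the majority target, so every prediction is "dead"
  co <- generate_cohort(n = 398, seed = 6, exact_counts = TRUE)
  dat <- list(X = matrix(0, 398, 4), y = cohort_labels(co))
  cfg <- trainer_config(network_spec(c(4, 1)), N = 8, T = 10, seed = 1)
  cv <- cross_validate(dat, cfg, k = 5, seed = 3)
  # across-fold mean of per-fold majority shares differs from the
  # global share only by fold-size rounding (~4e-6)
  expect_equal(cv$mean$Acc, 297 / 398, tolerance = 1e-4)
  expect_length(cv$folds, 5)
})

test_that("mean ROC vertical averaging stays within [0,1] and brackets folds", {
  rocs <- list(data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1)),
               data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.6, 1)))
  mr <- mean_roc(rocs, grid = c(0, 0.5, 1))
  expect_equal(mr$tpr, c(0, 0.7, 1))
})
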
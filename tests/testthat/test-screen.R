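test_that("outcome labels follow the >=26 fail rule and 20-35 gray zone", {
  lab <- label_outcome(c(0, 19, 20, 25, 26, 35, 36, 50))
  expect_equal(lab$label,
               c("pass", "pass", "pass", "pass", "fail", "fail", "fail", "fail"))
  expect_equal(lab$gray_zone,
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(label_outcome(-1), ">= 0")
})

test_that("screening metrics reproduce both published worked examples", {
  # time series clustering + logistic regression
  m1 <- screening_metrics(confusion_matrix(FF = 110, FP = 41,
                                           PF = 986, PP = 3171))
  expect_equal(round_half_away(m1$rr, 3), 3.071)
  expect_equal(round_half_away(m1$rr_ci, 3), c(2.747, 3.434))
  expect_equal(round_half_away(100 * m1$accuracy, 1), 76.2)
  expect_equal(round_half_away(100 * m1$ratio_false_alarms, 1), 27.2)
  expect_equal(round_half_away(100 * m1$tpr, 1), 10.0)
  expect_equal(round_half_away(100 * m1$fpr, 1), 1.3)
  # variables + logistic regression
  m2 <- screening_metrics(confusion_matrix(FF = 174, FP = 109,
                                           PF = 922, PP = 3103))
  expect_equal(round_half_away(m2$rr, 3), 2.684)
  expect_equal(round_half_away(m2$rr_ci, 3), c(2.409, 2.991))
  expect_equal(round_half_away(100 * m2$ratio_false_alarms, 1), 38.5)
  expect_equal(round_half_away(100 * m2$fail_rate, 1), 6.6)
})

test_that("metric identities and degenerate classifiers behave", {
  cm <- confusion_matrix(FF = 30, FP = 10, PF = 20, PP = 140)
  m <- screening_metrics(cm)
  expect_equal(m$fail_rate, m$false_alarm_rate + cm[["FF"]] / m$n)
  expect_equal(m$tpr * (cm[["FF"]] + cm[["PF"]]), cm[["FF"]])
  expect_true(m$rr_ci[1] <= m$rr && m$rr <= m$rr_ci[2])

  perfect <- screening_metrics(confusion_matrix(50, 0, 0, 150),
                               strict = FALSE)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$ratio_false_alarms, 0)
  expect_true(perfect$rr_infinite)

  expect_error(screening_metrics(confusion_matrix(0, 0, 30, 70)),
               "undefined")
  loose <- screening_metrics(confusion_matrix(0, 0, 30, 70), strict = FALSE)
  expect_true(is.nan(loose$rr))
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(2.25, 1), 2.3)
  expect_equal(round_half_away(-2.25, 1), -2.3)
  expect_equal(round_half_away(2.249, 1), 2.2)
  expect_equal(round_half_away(92.75, 1), 92.8)
})

test_that("confusion reconstruction recovers the published matrices", {
  cm1 <- reconstruct_confusion(4308, 1096,
                               c(tpr = 10.0, fpr = 1.3,
                                 ratio_false_alarms = 27.2))
  expect_equal(unclass(cm1)[c("FF", "FP", "PF", "PP")],
               c(FF = 110L, FP = 41L, PF = 986L, PP = 3171L))
  cm2 <- reconstruct_confusion(4308, 1096,
                               c(tpr = 15.9, fpr = 3.4, fail_rate = 6.6,
                                 accuracy = 76.1))
  expect_equal(unclass(cm2)[c("FF", "FP", "PF", "PP")],
               c(FF = 174L, FP = 109L, PF = 922L, PP = 3103L))
})

test_that("under-determined or unsatisfiable constraints raise errors", {
  expect_error(reconstruct_confusion(4308, 1096, c(tpr = 10.0)),
               "ambiguous|too weak")
  # tpr 15.9 + fpr 3.4 + fail rate 6.6 admits two integer matrices
  expect_error(reconstruct_confusion(4308, 1096,
                                     c(tpr = 15.9, fpr = 3.4,
                                       fail_rate = 6.6)),
               "ambiguous")
  expect_error(reconstruct_confusion(100, 50, c(tpr = 99.9, fpr = 0.1,
                                                accuracy = 1)),
               "no integer")
})

test_that("roc_auc handles the chance line, a perfect curve, and matches
           numerical integration", {
  expect_equal(roc_auc(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(roc_auc(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1.0)
  set.seed(9)
  for (rep in 1:5) {
    fpr <- sort(c(0, runif(8), 1))
    tpr <- sort(c(0, runif(8), 1))
    expect_equal(roc_auc(data.frame(fpr = fpr, tpr = tpr)),
                 oracle_trapezoid(fpr, tpr), tolerance = 1e-10)
  }
})

test_that("stratified folds keep both classes everywhere and error when
           impossible", {
  y <- rep(c(TRUE, FALSE), c(30, 70))
  id <- stratified_folds(y, 10, seed = 1)
  expect_true(all(table(id, y) > 0))
  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 97)), 10, seed = 1),
               "stratification error")
})

test_that("logistic threshold sweep has the right endpoints and is monotone", {
  set.seed(42)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  y <- runif(n) < plogis(X %*% c(2, -1, 1, 0, 0) - 0.8)
  sw <- logistic_sweep(X, y, folds = 5, seed = 3)
  m <- sw$metrics
  tau0 <- m[m$threshold == 0, ]
  expect_equal(tau0$fail_rate, 1)
  expect_equal(tau0$tpr, 1)
  expect_equal(tau0$fpr, 1)
  top <- m[nrow(m), ]  # tau = 1 > max predicted probability
  expect_equal(top$fpr, 0)
  expect_equal(top$tpr, 0)
  # increasing tau never increases tpr or fpr
  expect_true(all(diff(m$tpr) <= 1e-12))
  expect_true(all(diff(m$fpr) <= 1e-12))
  expect_gt(sw$auc, 0.8)  # strong planted signal
  expect_error(logistic_sweep(X, rep(TRUE, n)), "both classes")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(11)
  n <- 2000
  X <- matrix(rnorm(n * 20), n, 20)
  y <- sample(rep(c(TRUE, FALSE), c(500, 1500)))  # independent of X
  sw <- logistic_sweep(X, y, folds = 10, seed = 5)
  expect_gt(sw$auc, 0.45)
  expect_lt(sw$auc, 0.55)
})

test_that("svm grid covers the dyadic ranges and solves a separable problem", {
  g <- expand.grid(gamma = 2^(-10:6), cost = 2^(-5:15))
  expect_equal(length(2^(-10:6)), 17L)
  expect_equal(length(2^(-5:15)), 21L)
  expect_equal(nrow(g), 357L)

  set.seed(8)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2) + 6 * cbind(y, y)
  out <- svm_grid(X, y, folds = 5, gammas = 2^(-4:0), costs = 2^(0:4),
                  seed = 2)
  expect_equal(nrow(out), 25L)
  expect_gte(max(out$accuracy), 0.95)
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
  expect_true(all(out$fail_rate >= out$false_alarm_rate - 1e-12))
})

test_that("missing features are mean-imputed from training folds", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  y <- runif(n) < plogis(2 * X[, 1])
  X[sample(n, 50), 3] <- NA
  sw <- logistic_sweep(X, y, folds = 5, seed = 9)
  expect_false(anyNA(sw$probs))
})
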
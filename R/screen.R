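#' Label an on-road-exam score
#'
#' A score of 26 or more fails the exam (0 is a perfect score); the "gray
#' zone" of scores 20-35 marks drivers who barely pass or barely fail.
#'
#' @param score non-negative integer score(s).
#' @return data.frame with columns `score`, `label` (`"pass"/"fail"`),
#'   `gray_zone` (logical).
#' @export
#' @examples
#' label_outcome(c(0, 25, 26, 35))
label_outcome <- function(score) {
  if (any(is.na(score)) || any(score < 0)) stop("score must be >= 0")
  data.frame(score = score,
             label = ifelse(score >= 26, "fail", "pass"),
             gray_zone = score >= 20 & score <= 35)
}

#' Construct a screening confusion matrix
#'
#' Cells are named prediction-then-outcome: `FF` (predicted fail, failed),
#' `FP` (predicted fail, passed), `PF` (predicted pass, failed), `PP`
#' (predicted pass, passed).
#'
#' @param FF,FP,PF,PP non-negative integer cell counts.
#' @return a `confusion_matrix` (named integer vector with class attribute).
#' @export
confusion_matrix <- function(FF, FP, PF, PP) {
  cells <- c(FF = FF, FP = FP, PF = PF, PP = PP)
  if (any(is.na(cells)) || any(cells < 0)) stop("cells must be >= 0")
  structure(as.integer(round(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param predicted_fail,actual_fail logical vectors.
#' @export
confusion_from_predictions <- function(predicted_fail, actual_fail) {
  confusion_matrix(FF = sum(predicted_fail & actual_fail),
                   FP = sum(predicted_fail & !actual_fail),
                   PF = sum(!predicted_fail & actual_fail),
                   PP = sum(!predicted_fail & !actual_fail))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("          fail ORE  pass ORE\n")
  cat(sprintf("fail VDT %9d %9d\n", x["FF"], x["FP"]))
  cat(sprintf("pass VDT %9d %9d\n", x["PF"], x["PP"]))
  invisible(x)
}

#' The screening metric suite for a confusion matrix
#'
#' Computes accuracy `(FF+PP)/N`, algorithm fail rate `(FF+FP)/N`, false
#' alarm rate `FP/N`, ratio of false alarms `FP/(FF+FP)`, sensitivity
#' `TPR = FF/(FF+PF)`, `FPR = FP/(FP+PP)`, and the risk ratio of failing the
#' on-road exam when predicted fail versus predicted pass,
#' `RR = [FF/(FF+FP)] / [PF/(PF+PP)]`, with a Katz log-normal 95% CI:
#' `exp(log RR +- 1.96 * sqrt(1/FF - 1/(FF+FP) + 1/PF - 1/(PF+PP)))`.
#'
#' With no predicted fails the risk ratio is undefined: an error when
#' `strict = TRUE` (the default), otherwise `NaN` with `rr_defined = FALSE`.
#' With `PF = 0` the risk ratio is infinite and flagged via
#' `rr_infinite = TRUE`.
#'
#' @param cm a `confusion_matrix`.
#' @param strict error on an undefined risk ratio (default `TRUE`).
#' @return list of class `screening_metrics`: `accuracy`, `fail_rate`,
#'   `false_alarm_rate`, `ratio_false_alarms`, `tpr`, `fpr` (fractions),
#'   `rr`, `rr_ci` (length-2), `rr_defined`, `rr_infinite`, `n`.
#' @export
screening_metrics <- function(cm, strict = TRUE) {
  FF <- as.numeric(cm[["FF"]]); FP <- as.numeric(cm[["FP"]])
  PF <- as.numeric(cm[["PF"]]); PP <- as.numeric(cm[["PP"]])
  N <- FF + FP + PF + PP
  if (N <= 0) stop("empty confusion matrix")
  pred_fail <- FF + FP
  rr_defined <- pred_fail > 0 && (PF + PP) > 0
  if (!rr_defined && strict)
    stop("risk ratio undefined: no predicted fails (FF + FP = 0)")
  rr <- if (!rr_defined) NaN else if (PF == 0) Inf else
    (FF / pred_fail) / (PF / (PF + PP))
  rr_ci <- c(NA_real_, NA_real_)
  if (rr_defined && is.finite(rr) && FF > 0 && PF > 0) {
    se <- sqrt(1 / FF - 1 / pred_fail + 1 / PF - 1 / (PF + PP))
    rr_ci <- exp(log(rr) + c(-1, 1) * 1.96 * se)
  }
  structure(list(
    accuracy = (FF + PP) / N,
    fail_rate = pred_fail / N,
    false_alarm_rate = FP / N,
    ratio_false_alarms = if (pred_fail > 0) FP / pred_fail else NaN,
    tpr = if (FF + PF > 0) FF / (FF + PF) else NaN,
    fpr = if (FP + PP > 0) FP / (FP + PP) else NaN,
    rr = rr, rr_ci = rr_ci,
    rr_defined = rr_defined, rr_infinite = is.infinite(rr),
    n = N), class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  fail rate %.1f%%  false alarm rate %.1f%%\n",
              100 * x$accuracy, 100 * x$fail_rate, 100 * x$false_alarm_rate))
  cat(sprintf("ratio of false alarms %.1f%%  TPR %.1f%%  FPR %.1f%%\n",
              100 * x$ratio_false_alarms, 100 * x$tpr, 100 * x$fpr))
  cat(sprintf("risk ratio %.3f (95%% CI %.3f-%.3f)\n",
              x$rr, x$rr_ci[1], x$rr_ci[2]))
  invisible(x)
}

#' Round half away from zero
#'
#' The rounding convention used when reproducing printed (percent-scale)
#' metrics: `round_half_away(2.25, 1) == 2.3`.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reconstruct an integer confusion matrix from rounded printed metrics
#'
#' Exhaustively searches integer cell counts `(FF, FP)` with
#' `PF = n_fail - FF` and `PP = N - n_fail - FP` such that every constrained
#' metric — computed exactly, then rounded half away from zero to one
#' decimal on the percent scale — equals its printed value. Errors if no or
#' multiple matrices satisfy the constraints (listing the candidates).
#'
#' @param N total sample size.
#' @param n_fail number of drivers who actually failed.
#' @param constraints named numeric vector/list of printed percent values;
#'   names among `accuracy`, `fail_rate`, `false_alarm_rate`,
#'   `ratio_false_alarms`, `tpr`, `fpr`.
#' @return the unique `confusion_matrix`.
#' @export
#' @examples
#' reconstruct_confusion(4308, 1096,
#'   c(tpr = 10.0, fpr = 1.3, ratio_false_alarms = 27.2))
reconstruct_confusion <- function(N, n_fail, constraints) {
  constraints <- unlist(constraints)
  allowed <- c("accuracy", "fail_rate", "false_alarm_rate",
               "ratio_false_alarms", "tpr", "fpr")
  if (!length(constraints) || !all(names(constraints) %in% allowed))
    stop("constraints must be named among: ", paste(allowed, collapse = ", "))
  n_pass <- N - n_fail
  FFs <- 0:n_fail
  FPs <- 0:n_pass
  eq <- function(x, v) !is.na(x) & round_half_away(x, 1) == v
  if ("tpr" %in% names(constraints))
    FFs <- FFs[eq(100 * FFs / n_fail, constraints[["tpr"]])]
  if ("fpr" %in% names(constraints))
    FPs <- FPs[eq(100 * FPs / n_pass, constraints[["fpr"]])]
  if (as.double(length(FFs)) * length(FPs) > 2e7)
    stop("constraints too weak: search grid of ",
         length(FFs), " x ", length(FPs), " candidates")
  grid <- expand.grid(FF = FFs, FP = FPs)
  ok <- rep(TRUE, nrow(grid))
  FF <- grid$FF; FP <- grid$FP
  val <- list(
    accuracy = 100 * (FF + (n_pass - FP)) / N,
    fail_rate = 100 * (FF + FP) / N,
    false_alarm_rate = 100 * FP / N,
    ratio_false_alarms = ifelse(FF + FP > 0, 100 * FP / (FF + FP), NA),
    tpr = 100 * FF / n_fail,
    fpr = 100 * FP / n_pass)
  for (nm in names(constraints))
    ok <- ok & eq(val[[nm]], constraints[[nm]])
  hits <- grid[ok, , drop = FALSE]
  if (nrow(hits) == 0)
    stop("no integer confusion matrix reproduces the printed metrics")
  if (nrow(hits) > 1)
    stop("ambiguous reconstruction; candidates (FF, FP): ",
         paste(sprintf("(%d, %d)", hits$FF, hits$FP), collapse = " "))
  confusion_matrix(FF = hits$FF, FP = hits$FP,
                   PF = n_fail - hits$FF, PP = n_pass - hits$FP)
}

#' Trapezoidal area under an ROC curve
#'
#' Points are sorted by FPR (then TPR); the endpoints (0,0) and (1,1) are
#' added if absent. The AUC is the trapezoidal integral of TPR over FPR.
#'
#' @param points data.frame (or matrix) with columns `fpr`, `tpr`.
#' @return scalar AUC in \[0,1\].
#' @export
roc_auc <- function(points) {
  pts <- as.data.frame(points)[, c("fpr", "tpr")]
  pts <- pts[is.finite(pts$fpr) & is.finite(pts$tpr), ]
  if (!any(pts$fpr == 0 & pts$tpr == 0)) pts <- rbind(pts, c(0, 0))
  if (!any(pts$fpr == 1 & pts$tpr == 1)) pts <- rbind(pts, c(1, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' Stratified cross-validation fold assignment
#'
#' @param actual_fail logical outcome per sample.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold id per sample; errors if any fold would be
#'   single-class.
#' @export
stratified_folds <- function(actual_fail, folds = 10L, seed = 1L) {
  set.seed(seed)
  id <- integer(length(actual_fail))
  for (cls in unique(actual_fail)) {
    idx <- sample(which(actual_fail == cls))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  tab <- table(factor(id, seq_len(folds)), actual_fail)
  if (any(tab == 0))
    stop("stratification error: some fold would contain a single class ",
         "(", sum(actual_fail), " fails over ", folds, " folds)")
  id
}

# Mean-impute missing feature entries using training-fold column means.
impute_by_train_means <- function(X_train, X_test = NULL) {
  mu <- colMeans(X_train, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  fill <- function(X) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mu[j]
    }
    X
  }
  list(train = fill(X_train),
       test = if (is.null(X_test)) NULL else fill(X_test), means = mu)
}

# Out-of-fold P(fail) from a ridge-penalized logistic fit. With
# ridge = NULL (default) the penalty is selected per training fold by an
# inner cross-validation (cv.glmnet, lambda.min); a numeric ridge fixes the
# penalty instead. Near-zero fixed penalties approximate the plain
# maximum-likelihood fit but are numerically fragile on wide correlated
# feature blocks. fold_features, if given, supplies per-fold (train, test)
# matrices for pipelines whose features themselves depend on the fold.
cv_logistic_probs <- function(features, actual_fail, fold_id,
                              ridge = NULL, fold_features = NULL, seed = 1L) {
  n <- length(actual_fail)
  probs <- rep(NA_real_, n)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    if (is.null(fold_features)) {
      Xtr <- features[!te, , drop = FALSE]
      Xte <- features[te, , drop = FALSE]
    } else {
      Xtr <- fold_features[[f]]$train
      Xte <- fold_features[[f]]$test
    }
    imp <- impute_by_train_means(Xtr, Xte)
    ytr <- factor(actual_fail[!te], c(FALSE, TRUE))
    if (is.null(ridge)) {
      set.seed(derive_seed(seed, 9000 + f))
      fit <- glmnet::cv.glmnet(imp$train, ytr, family = "binomial",
                               alpha = 0, nfolds = 5,
                               lambda = 10^seq(1.5, -4, length.out = 40),
                               standardize = TRUE)
      probs[te] <- as.numeric(predict(fit, imp$test, type = "response",
                                      s = "lambda.min"))
    } else {
      fit <- glmnet::glmnet(imp$train, ytr, family = "binomial", alpha = 0,
                            lambda = ridge, standardize = TRUE)
      probs[te] <- as.numeric(predict(fit, imp$test, type = "response"))
    }
  }
  probs
}

#' Logistic decision-rule threshold sweep with cross-validation
#'
#' Fits a ridge-stabilized logistic model under stratified k-fold
#' cross-validation, pools the out-of-fold predicted fail probabilities, and
#' sweeps the decision threshold tau over \[0,1\]: a driver is predicted to
#' fail iff `P(fail) >= tau`. Emits the full screening metric suite per
#' threshold plus the ROC curve and its trapezoidal AUC.
#'
#' @param features numeric matrix (drives x features); `NA` entries are mean
#'   imputed per column from the training folds.
#' @param actual_fail logical outcome per drive.
#' @param folds number of stratified CV folds (default 10).
#' @param thresholds decision thresholds (default 0 to 1, step 0.01).
#' @param seed integer seed for fold assignment and the inner penalty
#'   selection.
#' @param ridge L2 penalty: `NULL` (default) selects it per training fold by
#'   inner cross-validation; a numeric value fixes it (e.g. `1e-8` for a
#'   near-unpenalized maximum-likelihood fit).
#' @param fold_features optional per-fold feature list (see
#'   `cv_logistic_probs`), for features that are themselves fold dependent.
#' @return list of class `threshold_sweep`: `metrics` (data.frame per tau),
#'   `roc` (fpr/tpr/tau points), `auc`, `probs`, `fold_id`.
#' @export
logistic_sweep <- function(features, actual_fail, folds = 10L,
                           thresholds = seq(0, 1, by = 0.01), seed = 1L,
                           ridge = NULL, fold_features = NULL) {
  if (length(unique(actual_fail)) < 2) stop("need both classes present")
  fold_id <- stratified_folds(actual_fail, folds, seed)
  probs <- cv_logistic_probs(features, actual_fail, fold_id, ridge,
                             fold_features, seed = seed)
  rows <- lapply(thresholds, function(tau) {
    m <- screening_metrics(
      confusion_from_predictions(probs >= tau, actual_fail), strict = FALSE)
    data.frame(threshold = tau, accuracy = m$accuracy,
               fail_rate = m$fail_rate, false_alarm_rate = m$false_alarm_rate,
               ratio_false_alarms = m$ratio_false_alarms,
               tpr = m$tpr, fpr = m$fpr, rr = m$rr,
               rr_lo = m$rr_ci[1], rr_hi = m$rr_ci[2])
  })
  metrics <- do.call(rbind, rows)
  roc <- metrics[, c("fpr", "tpr", "threshold")]
  structure(list(metrics = metrics, roc = roc, auc = roc_auc(roc),
                 probs = probs, fold_id = fold_id),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  cat(sprintf("<threshold_sweep> %d thresholds, AUC %.3f\n",
              nrow(x$metrics), x$auc))
  cat(sprintf("  best accuracy %.1f%% at tau = %.2f\n",
              100 * best$accuracy, best$threshold))
  invisible(x)
}

#' RBF-SVM dyadic grid search with cross-validation
#'
#' For every (cost, gamma) cell of the dyadic grids, fits a radial-basis
#' SVM under stratified k-fold cross-validation and evaluates the pooled
#' out-of-fold predictions with the screening metric suite. Default grids:
#' gamma doubling over 2^-10..2^6 (17 values), cost doubling over
#' 2^-5..2^15 (21 values).
#'
#' @inheritParams logistic_sweep
#' @param gammas,costs dyadic parameter grids.
#' @return data.frame with one row per grid cell (`gamma`, `cost`, metric
#'   columns), with attribute `fold_id`.
#' @export
svm_grid <- function(features, actual_fail, folds = 10L,
                     gammas = 2^(-10:6), costs = 2^(-5:15), seed = 1L) {
  if (length(unique(actual_fail)) < 2) stop("need both classes present")
  fold_id <- stratified_folds(actual_fail, folds, seed)
  y <- factor(ifelse(actual_fail, "fail", "pass"), c("fail", "pass"))
  # impute once per fold (imputation is parameter free)
  fold_data <- lapply(sort(unique(fold_id)), function(f) {
    te <- fold_id == f
    imp <- impute_by_train_means(features[!te, , drop = FALSE],
                                 features[te, , drop = FALSE])
    list(train = imp$train, test = imp$test, ytr = y[!te], te = te)
  })
  grid <- expand.grid(gamma = gammas, cost = costs)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    pred_fail <- rep(NA, length(y))
    for (fd in fold_data) {
      fit <- e1071::svm(fd$train, fd$ytr, kernel = "radial",
                        gamma = grid$gamma[g], cost = grid$cost[g],
                        scale = apply(fd$train, 2, var) > 0)
      pred_fail[fd$te] <- predict(fit, fd$test) == "fail"
    }
    m <- screening_metrics(confusion_from_predictions(pred_fail, actual_fail),
                           strict = FALSE)
    data.frame(gamma = grid$gamma[g], cost = grid$cost[g],
               accuracy = m$accuracy, fail_rate = m$fail_rate,
               false_alarm_rate = m$false_alarm_rate,
               ratio_false_alarms = m$ratio_false_alarms,
               tpr = m$tpr, fpr = m$fpr, rr = m$rr)
  })
  out <- do.call(rbind, rows)
  attr(out, "fold_id") <- fold_id
  out
}
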
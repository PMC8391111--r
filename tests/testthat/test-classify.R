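quick_reducer <- function(seed = 1) {
  reducer_config(hidden = c(16, 8, 4), epochs = 150, learning_rate = 0.3,
                 min_epochs = 50, n_restarts = 1, seed = seed)
}
quick_config <- function(seed = 1) {
  classifier_config(cost_grid = 2^seq(-3, 5, 4),
                    reducer = quick_reducer(seed), seed = seed)
}

test_that("mask thresholds are training medians with >= mapping to 1", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10))
  mask <- fit_mask(x)
  expect_equal(unname(mask$thresholds), c(2.5, 10))
  out <- apply_mask(mask, cbind(a = c(3, 2), b = c(9, 11)))
  expect_equal(unname(out[, "a"]), c(1, 0))
  expect_equal(unname(out[, "b"]), c(0, 1))
  # constant feature maps to all ones
  expect_equal(unname(apply_mask(mask, x)[, "b"]), rep(1, 4))
  # rank invariance: monotone transforms leave the binary output alone
  expect_equal(apply_mask(fit_mask(exp(x)), exp(x)),
               apply_mask(mask, x))
  # train == test reproduces the training mask output
  expect_equal(apply_mask(mask, x), apply_mask(fit_mask(x), x))
})

test_that("reducer training is deterministic, shaped, and loss-decreasing", {
  pf <- prototype_features(n = 60, d = 30, seed = 2)
  net1 <- train_reducer(pf$x, pf$y, quick_reducer(7))
  net2 <- train_reducer(pf$x, pf$y, quick_reducer(7))
  expect_identical(net1$W1, net2$W1)
  expect_identical(net1$W3, net2$W3)
  expect_equal(dim(net1$W1), c(30, 16))
  expect_equal(dim(net1$W3), c(8, 4))
  expect_lt(net1$loss[length(net1$loss)], net1$loss[1])
  expect_true(all(is.finite(unlist(net1[c("W1", "W2", "W3")]))))
  codes <- encode(net1, pf$x)
  expect_equal(dim(codes), c(60, 4))
  expect_true(all(codes >= 0 & codes <= 1))
})

test_that("two-stage pipeline recovers linearly separable binary prototypes", {
  pf <- prototype_features(n = 100, d = 40, flip = 0.05, seed = 3)
  # nearest-prototype oracle is near-perfect on this data
  proto <- rbind(rep(c(1, 0), length.out = 40), rep(c(0, 1), length.out = 40))
  d2 <- cbind(rowSums(sweep(pf$x, 2, proto[1, ])^2),
              rowSums(sweep(pf$x, 2, proto[2, ])^2))
  oracle_acc <- mean(c("case", "control")[apply(d2, 1, which.min)] == pf$y)
  expect_gte(oracle_acc, 0.95)
  rep2 <- two_stage_cv(pf$x, pf$y, quick_config(5), keep_models = FALSE)
  expect_gte(rep2$metrics[["balanced_accuracy"]], 0.9)
})

test_that("baseline SVM separates two well-separated Gaussian classes", {
  set.seed(6)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = 10), ncol = 5))
  colnames(x) <- paste0("f", 1:5)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  report <- baseline_svm_cv(x, y, quick_config(2), keep_models = FALSE)
  expect_gte(report$metrics[["accuracy"]], 0.95)
})

test_that("null labels give chance-level accuracy for both models", {
  set.seed(8)
  x <- matrix(rnorm(40 * 25), 40, 25)
  colnames(x) <- paste0("f", 1:25)
  bal2 <- bal1 <- numeric(5)
  for (i in 1:5) {
    set.seed(100 + i)
    y <- factor(sample(rep(c("control", "case"), 20)),
                levels = c("control", "case"))
    bal2[i] <- two_stage_cv(x, y, quick_config(i),
                            keep_models = FALSE)$metrics[["balanced_accuracy"]]
    bal1[i] <- baseline_svm_cv(x, y, quick_config(i),
                               keep_models = FALSE)$metrics[["balanced_accuracy"]]
  }
  expect_true(all(bal2 >= 0.25 & bal2 <= 0.75))
  expect_true(all(bal1 >= 0.25 & bal1 <= 0.75))
  expect_true(mean(c(bal2, bal1) >= 0.35 & c(bal2, bal1) <= 0.65) >= 0.8)
})

test_that("duplicated feature columns leave the two-stage report unchanged", {
  pf <- prototype_features(n = 60, d = 20, seed = 9)
  cfg <- quick_config(3)
  r1 <- two_stage_cv(pf$x, pf$y, cfg, keep_models = FALSE)
  xdup <- cbind(pf$x, pf$x)
  colnames(xdup) <- paste0("f", seq_len(ncol(xdup)))
  r2 <- two_stage_cv(xdup, pf$y, cfg, keep_models = FALSE)
  expect_equal(r1$folds, r2$folds)
  expect_equal(r1$metrics, r2$metrics, tolerance = 0.1)
})

test_that("shared folds make baseline and two-stage reports comparable", {
  pf <- prototype_features(n = 60, d = 20, seed = 10)
  cfg <- quick_config(4)
  folds <- make_stratified_folds(pf$y, 10, 4)
  r2 <- two_stage_cv(pf$x, pf$y, cfg, folds = folds, keep_models = FALSE)
  r1 <- baseline_svm_cv(pf$x, pf$y, cfg, folds = folds, keep_models = FALSE)
  expect_identical(r2$folds, r1$folds)
  expect_identical(r2$predictions$fold, r1$predictions$fold)
})

test_that("stratified folds keep both classes in every training set", {
  y <- factor(rep(c("case", "control"), c(30, 20)))
  folds <- make_stratified_folds(y, 10, 1)
  expect_equal(sort(unique(folds)), 1:10)
  for (f in 1:10)
    expect_setequal(unique(as.character(y[folds != f])),
                    c("case", "control"))
  y_bad <- factor(rep(c("case", "control"), c(1, 49)))
  expect_error(make_stratified_folds(y_bad, 10, 1), "stratification")
})

test_that("permutation p follows the counting rule and calibrates under the null", {
  # stated formula on synthetic permuted statistics
  obs <- 0.8
  perm <- c(rep(0.9, 12), rep(0.5, 988))
  expect_equal(sum(perm >= obs) / 1000, 0.012)
  expect_equal(sum(c(0.1, 0.2) >= 0.99) / 2, 0)  # p = 0 under the plain rule
  expect_error(
    permutation_test(matrix(rnorm(40), 20), rep(c("a", "b"), 10),
                     n_perm = -1),
    "positive integer")

  # calibration: on null data, small p occurs at roughly nominal rate
  set.seed(12)
  x <- matrix(rnorm(24 * 6), 24, 6)
  colnames(x) <- paste0("f", 1:6)
  cfg <- classifier_config(outer_folds = 4, inner_folds = 3,
                           cost_grid = 1, reducer = quick_reducer(1),
                           seed = 1)
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    y <- factor(sample(rep(c("control", "case"), 12)),
                levels = c("control", "case"))
    pt <- permutation_test(x, y, cfg, model = "baseline", n_perm = 19,
                           seed = s)
    if (pt$p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 3)
})

test_that("corrupting test-fold labels never changes that fold's fitted models", {
  pf <- prototype_features(n = 60, d = 25, seed = 13)
  cfg <- quick_config(6)
  folds <- make_stratified_folds(pf$y, 10, 6)
  r_clean <- two_stage_cv(pf$x, pf$y, cfg, folds = folds)
  b_clean <- baseline_svm_cv(pf$x, pf$y, cfg, folds = folds)
  # fold f's models are fitted on the other folds only, so flipping every
  # label inside fold f must leave fold f's mask/reducer/scaler/SVM
  # byte-identical
  for (f in 1:3) {
    y_bad <- pf$y
    idx <- which(folds == f)
    y_bad[idx] <- factor(ifelse(pf$y[idx] == "case", "control", "case"),
                         levels = levels(pf$y))
    r_bad <- two_stage_cv(pf$x, y_bad, cfg, folds = folds)
    expect_identical(r_clean$models[[f]]$mask, r_bad$models[[f]]$mask)
    expect_identical(r_clean$models[[f]]$reducer$W1,
                     r_bad$models[[f]]$reducer$W1)
    expect_identical(r_clean$models[[f]]$reducer$W3,
                     r_bad$models[[f]]$reducer$W3)
    expect_identical(r_clean$models[[f]]$scaler, r_bad$models[[f]]$scaler)
    expect_identical(r_clean$models[[f]]$cost, r_bad$models[[f]]$cost)
    expect_identical(r_clean$models[[f]]$svm_w, r_bad$models[[f]]$svm_w)
    b_bad <- baseline_svm_cv(pf$x, y_bad, cfg, folds = folds)
    expect_identical(b_clean$models[[f]]$scaler, b_bad$models[[f]]$scaler)
    expect_identical(b_clean$models[[f]]$svm_w, b_bad$models[[f]]$svm_w)
  }
})

test_that("primal-weight prediction equals predict.svm for linear kernels", {
  set.seed(15)
  for (i in 1:5) {
    x <- matrix(rnorm(50 * 6), 50, 6)
    y <- factor(sample(rep(c("control", "case"), 25)),
                levels = sample(c("control", "case")))
    fit <- e1071::svm(x, y, kernel = "linear", cost = 2^sample(-3:3, 1),
                      scale = FALSE)
    xt <- matrix(rnorm(30 * 6), 30, 6)
    expect_equal(connectoclass:::predict_linear_svm(fit, xt),
                 as.character(predict(fit, xt)))
  }
})

test_that("classification metrics use case as the positive class", {
  truth <- c("case", "case", "control", "control", "control")
  pred <- c("case", "control", "control", "control", "case")
  m <- classification_metrics(truth, pred, "case")
  expect_equal(m[["sensitivity"]], 1 / 2)
  expect_equal(m[["specificity"]], 2 / 3)
  expect_equal(m[["balanced_accuracy"]], (1 / 2 + 2 / 3) / 2)
  expect_equal(m[["accuracy"]], 3 / 5)
})
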
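#' Classifier configuration
#'
#' Settings for the two-stage pipeline and the baseline SVM: 10-fold
#' stratified outer cross-validation for assessment, 5-fold inner
#' cross-validated grid search over the linear-SVM cost C (selection by
#' balanced accuracy, ties resolved toward the smallest C), and
#' training-fold z-scoring before the SVM.
#'
#' @param outer_folds,inner_folds fold counts.
#' @param cost_grid candidate SVM costs (default `2^seq(-5, 15, 2)`).
#' @param reducer a [reducer_config()] for the two-stage model.
#' @param positive name of the positive class (defaults to `"case"`
#'   when present, otherwise the second factor level).
#' @param seed seed driving fold assignment and per-fold reducer
#'   initialization.
#' @return a `classifier_config`.
#' @export
classifier_config <- function(outer_folds = 10, inner_folds = 5,
                              cost_grid = 2^seq(-5, 15, by = 2),
                              reducer = reducer_config(),
                              positive = NULL, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, length(cost_grid) >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 cost_grid = sort(cost_grid), reducer = reducer,
                 positive = positive, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit the binary masking operator
#'
#' Per-feature threshold set to the training-set median; applying the
#' mask maps a value to 1 when it is greater than or equal to the
#' threshold, else 0. Thresholds are estimated exclusively from
#' training rows. A constant feature yields an all-ones column for that
#' feature.
#'
#' @param train_features training matrix (rows = subjects).
#' @return a `mask_operator` with the threshold vector.
#' @export
fit_mask <- function(train_features) {
  x <- as.matrix(train_features)
  stopifnot(nrow(x) >= 2)
  structure(list(thresholds = apply(x, 2, median),
                 feature_names = colnames(x)),
            class = "mask_operator")
}

#' Apply a fitted binary mask
#'
#' @param mask a [fit_mask()] result.
#' @param x feature matrix with the same columns.
#' @return 0/1 matrix of the same shape.
#' @export
apply_mask <- function(mask, x) {
  stopifnot(inherits(mask, "mask_operator"))
  x <- as.matrix(x)
  out <- (x >= matrix(mask$thresholds, nrow(x), ncol(x),
                      byrow = TRUE)) * 1
  dimnames(out) <- dimnames(x)
  out
}

#' Stratified fold assignment
#'
#' @param y label factor/vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_stratified_folds <- function(y, k, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (length(unique(y[folds != f])) < length(unique(y)))
      stop("stratification error: a class is absent from the training ",
           "set of fold ", f)
  }
  folds
}

positive_class <- function(y, positive = NULL) {
  lv <- levels(as.factor(y))
  if (!is.null(positive)) {
    stopifnot(positive %in% lv)
    positive
  } else if ("case" %in% lv) "case" else lv[2]
}

#' Classification metrics from pooled predictions
#'
#' Sensitivity is TP/(TP+FN) with the positive ("case") class as
#' positive; balanced accuracy is the mean of sensitivity and
#' specificity.
#'
#' @param truth,pred label vectors.
#' @param positive positive class name.
#' @return named numeric vector (accuracy, sensitivity, specificity,
#'   balanced_accuracy).
#' @export
classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(accuracy = (tp + tn) / length(truth), sensitivity = sens,
    specificity = spec, balanced_accuracy = (sens + spec) / 2)
}

scale_train <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scale <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")
}

svm_weights <- function(model) {
  w <- t(model$coefs) %*% model$SV
  as.numeric(w)
}

# linear-SVM prediction straight from the primal weights: identical to
# predict.svm for kernel = "linear" but without the model-frame
# overhead, which dominates in the inner grid search
predict_linear_svm <- function(fit, x) {
  dv <- as.numeric(x %*% (t(fit$coefs) %*% fit$SV)[1, ]) - fit$rho
  pos <- fit$levels[fit$labels[1]]
  neg <- fit$levels[fit$labels[2]]
  ifelse(dv > 0, pos, neg)
}

# inner 5-fold grid search over cost on (already transformed) training
# data; returns the best cost (ties -> smallest)
grid_search_cost <- function(x, y, config, seed) {
  folds <- make_stratified_folds(y, config$inner_folds, seed)
  bal <- vapply(config$cost_grid, function(cost) {
    preds <- character(length(y))
    for (f in seq_len(config$inner_folds)) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      preds[!tr] <- predict_linear_svm(fit, x[!tr, , drop = FALSE])
    }
    classification_metrics(y, preds,
                           positive_class(y, config$positive))[["balanced_accuracy"]]
  }, 0)
  config$cost_grid[which.max(bal)]   # which.max takes the first (smallest C) tie
}

run_cv <- function(x, y, config, folds, model_tag, keep_models) {
  y <- droplevels(as.factor(y))
  stopifnot(nrow(x) >= 20, nlevels(y) == 2)
  if (is.null(folds))
    folds <- make_stratified_folds(y, config$outer_folds, config$seed)
  k <- max(folds)
  pos <- positive_class(y, config$positive)
  pred <- character(length(y))
  fold_models <- vector("list", k)
  fold_metrics <- matrix(NA_real_, k, 4)
  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]
    if (nlevels(droplevels(ytr)) < 2)
      stop("stratification error: a class is absent from the training ",
           "set of fold ", f)
    if (model_tag == "two-stage") {
      mask <- fit_mask(xtr)
      btr <- apply_mask(mask, xtr)
      bte <- apply_mask(mask, xte)
      rcfg <- config$reducer
      rcfg$seed <- config$reducer$seed + 7919L * f
      net <- train_reducer(btr, ytr, rcfg)
      ztr <- encode(net, btr); zte <- encode(net, bte)
    } else {
      mask <- NULL; net <- NULL
      ztr <- xtr; zte <- xte
    }
    sc <- scale_train(ztr)
    ztr <- apply_scale(ztr, sc); zte <- apply_scale(zte, sc)
    cost <- grid_search_cost(ztr, ytr, config,
                             seed = config$seed + 104729L + f)
    fit <- e1071::svm(ztr, ytr, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[!tr] <- predict_linear_svm(fit, zte)
    fold_metrics[f, ] <- classification_metrics(y[!tr], pred[!tr], pos)
    fold_models[[f]] <- if (keep_models)
      list(mask = mask, reducer = net, scaler = sc, cost = cost,
           svm_w = svm_weights(fit), svm_rho = fit$rho, svm = fit)
    else list(cost = cost)
  }
  pooled <- classification_metrics(y, pred, pos)
  colnames(fold_metrics) <- names(pooled)
  structure(list(
    model_tag = model_tag,
    metrics = pooled,
    fold_mean_metrics = colMeans(fold_metrics, na.rm = TRUE),
    fold_metrics = fold_metrics,
    predictions = data.frame(subject = rownames(x) %||%
                               seq_along(y), fold = folds,
                             truth = as.character(y), pred = pred,
                             stringsAsFactors = FALSE),
    folds = folds, positive = pos,
    chosen_costs = vapply(fold_models, `[[`, 0, "cost"),
    models = fold_models, config = config,
    permutation_p = NA_real_
  ), class = "classification_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-stage cross-validated classification
#'
#' The full prediction pipeline assessed by 10-fold stratified
#' cross-validation: inside each outer training fold a binary mask is
#' fitted (training median thresholds), the dimensionality-reduction
#' network is trained on the masked features, codes are z-scored with
#' training statistics, the linear-SVM cost is selected by 5-fold inner
#' grid search, and the final SVM is refitted on the full outer
#' training fold. Mask, reducer, scaler and cost are all fitted
#' strictly inside the outer training fold, so no information leaks
#' from test subjects.
#'
#' @param features numeric matrix (subjects by features) or a
#'   [cohort_features()] data frame.
#' @param labels label vector (ignored when `features` is a feature
#'   data frame).
#' @param config a [classifier_config()].
#' @param folds optional externally fixed fold assignment (integer
#'   vector); when NULL, stratified folds are drawn from the config
#'   seed.
#' @param keep_models keep per-fold fitted models in the report.
#' @return a `classification_report`: pooled and fold-mean accuracy /
#'   sensitivity / specificity / balanced accuracy, per-fold
#'   predictions, chosen costs and (optionally) fitted models.
#' @export
two_stage_cv <- function(features, labels = NULL,
                         config = classifier_config(), folds = NULL,
                         keep_models = TRUE) {
  fm <- resolve_features(features, labels)
  run_cv(fm$x, fm$y, config, folds, "two-stage", keep_models)
}

#' Baseline linear SVM on the raw feature vector
#'
#' Reference model: a linear SVM on the raw (training-fold z-scored)
#' graph features with the same outer folds and the same inner
#' grid-search protocol as the two-stage model, and no feature
#' selection.
#'
#' @inheritParams two_stage_cv
#' @return a `classification_report`.
#' @export
baseline_svm_cv <- function(features, labels = NULL,
                            config = classifier_config(), folds = NULL,
                            keep_models = TRUE) {
  fm <- resolve_features(features, labels)
  run_cv(fm$x, fm$y, config, folds, "baseline-svm", keep_models)
}

resolve_features <- function(features, labels) {
  if (is.data.frame(features) && "group" %in% names(features)) {
    fm <- feature_matrix(features)
  } else {
    fm <- list(x = as.matrix(features), y = labels)
  }
  stopifnot(!is.null(fm$y))
  fm
}

#' Permutation test of classification significance
#'
#' Group labels are randomly permuted before the entire
#' cross-validation procedure; this is repeated `n_perm` times and the
#' p-value is the number of permuted-label balanced accuracies greater
#' than or equal to the observed one, divided by `n_perm` (the plain
#' count rule, which can yield p = 0; set `smoothing = TRUE` for the
#' (b + 1)/(n + 1) variant).
#'
#' @param features,labels,config as in [two_stage_cv()].
#' @param model `"two-stage"` or `"baseline"`.
#' @param n_perm number of permutations (1000 in the full protocol).
#' @param observed observed balanced accuracy; computed from the real
#'   labels when NULL.
#' @param seed seed for the permutation stream.
#' @param smoothing use the add-one p-value variant.
#' @return a `permutation_test` list: `p`, `observed`, `perm_stats`.
#' @export
permutation_test <- function(features, labels = NULL,
                             config = classifier_config(),
                             model = c("two-stage", "baseline"),
                             n_perm = 1000, observed = NULL,
                             seed = NULL, smoothing = FALSE) {
  model <- match.arg(model)
  if (!(is.numeric(n_perm) && length(n_perm) == 1 && n_perm >= 1 &&
        n_perm == round(n_perm)))
    stop("n_perm must be a positive integer")
  fm <- resolve_features(features, labels)
  runner <- function(y, cfg) {
    if (model == "two-stage") run_cv(fm$x, y, cfg, NULL, "two-stage", FALSE)
    else run_cv(fm$x, y, cfg, NULL, "baseline-svm", FALSE)
  }
  if (is.null(observed))
    observed <- runner(fm$y, config)$metrics[["balanced_accuracy"]]
  if (is.null(seed)) seed <- config$seed
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 131071L + b)
    yp <- sample(fm$y)
    perm_stats[b] <- runner(yp, config)$metrics[["balanced_accuracy"]]
  }
  hits <- sum(perm_stats >= observed)
  p <- if (smoothing) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(p = p, observed = observed, perm_stats = perm_stats,
                 n_perm = n_perm, model = model),
            class = "permutation_test")
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<classification_report> %s\n  pooled: acc %.3f | sens %.3f | spec %.3f | bal %.3f\n",
    x$model_tag, m[1], m[2], m[3], m[4]))
  if (!is.na(x$permutation_p))
    cat(sprintf("  permutation p = %.3g\n", x$permutation_p))
  invisible(x)
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> %s: observed %.3f, p = %.3g (%d perms)\n",
              x$model, x$observed, x$p, x$n_perm))
  invisible(x)
}
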
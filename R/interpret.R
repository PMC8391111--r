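#' Backtrack weight contributions through the trained reducer
#'
#' Starting from the code layer l4 with uniform node contributions, the
#' contribution of each upstream node is the sum over the retained
#' downstream nodes of `|weight| * downstream contribution`. After each
#' layer only the minimal set of top-contribution nodes whose summed
#' contribution strictly exceeds 50% of the layer total is retained
#' (ties broken by node index); the calculation is propagated back to
#' the input layer, where the contributions of the raw features are
#' normalized to sum to 1 and ranked.
#'
#' @param net a [train_reducer()] result.
#' @param top_k number of top features to report (default 10).
#' @return a `contribution_ranking`: data frame `ranking` (rank,
#'   feature, score), full `scores` vector, and `kept` node sets per
#'   layer with their cumulative contribution fractions.
#' @export
backtrack_contributions <- function(net, top_k = 10) {
  stopifnot(inherits(net, "reducer_network"))
  weights <- list(net$W1, net$W2, net$W3)
  if (all(vapply(weights, function(w) all(w == 0), TRUE)))
    stop("all-zero weight matrices: contributions are undefined")
  h4 <- ncol(net$W3)
  contrib <- rep(1 / h4, h4)
  kept <- list()
  # retain-and-propagate from l4 down to l2
  for (layer in 3:1) {
    keep <- retain_half(contrib)
    kept[[paste0("l", layer + 1)]] <- keep
    w <- abs(weights[[layer]])
    upstream <- as.numeric(w[, keep$index, drop = FALSE] %*%
                             contrib[keep$index])
    if (sum(upstream) == 0)
      stop("zero total contribution at layer l", layer,
           ": contributions are undefined")
    contrib <- upstream
  }
  scores <- contrib / sum(contrib)
  nm <- net$feature_names %||% paste0("f", seq_along(scores))
  ord <- order(-scores, seq_along(scores))
  k <- min(top_k, length(scores))
  ranking <- data.frame(rank = seq_len(k), feature = nm[ord[seq_len(k)]],
                        score = scores[ord[seq_len(k)]],
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 scores = setNames(scores, nm),
                 kept = rev(kept), top_k = k, source = "reducer"),
            class = "contribution_ranking")
}

# minimal prefix (descending contribution, ties by index) whose sum is
# strictly greater than half the total
retain_half <- function(contrib) {
  ord <- order(-contrib, seq_along(contrib))
  cs <- cumsum(contrib[ord])
  total <- cs[length(cs)]
  m <- which(cs > total / 2)[1]
  idx <- sort(ord[seq_len(m)])
  list(index = idx, fraction = cs[m] / total)
}

#' Feature ranking of a fitted linear SVM
#'
#' The contribution of each input feature is the absolute value of its
#' primal weight `w = t(coefs) %*% SV`, normalized to sum to 1.
#'
#' @param model a fitted [e1071::svm()] with a linear kernel, or a
#'   `classification_report` from [baseline_svm_cv()] (fold-averaged
#'   absolute weights).
#' @param feature_names optional names.
#' @param top_k number of features to report.
#' @return a `contribution_ranking`.
#' @export
svm_feature_ranking <- function(model, feature_names = NULL,
                                top_k = 10) {
  if (inherits(model, "classification_report")) {
    stopifnot(model$model_tag == "baseline-svm")
    ws <- lapply(model$models, `[[`, "svm_w")
    if (any(vapply(ws, is.null, TRUE)))
      stop("report was run with keep_models = FALSE")
    w <- colMeans(do.call(rbind, lapply(ws, abs)))
    if (is.null(feature_names))
      feature_names <- colnames(model$models[[1]]$svm$SV)
  } else {
    if (!inherits(model, "svm") || model$kernel != 0)
      stop("unsupported model: need a linear-kernel svm")
    w <- abs(svm_weights(model))
    if (is.null(feature_names)) feature_names <- colnames(model$SV)
  }
  scores <- w / sum(w)
  nm <- feature_names %||% paste0("f", seq_along(scores))
  ord <- order(-scores, seq_along(scores))
  k <- min(top_k, length(scores))
  structure(list(
    ranking = data.frame(rank = seq_len(k), feature = nm[ord[seq_len(k)]],
                         score = scores[ord[seq_len(k)]],
                         stringsAsFactors = FALSE),
    scores = setNames(scores, nm), kept = list(), top_k = k,
    source = "svm"), class = "contribution_ranking")
}

#' Correlate top features with a symptom score
#'
#' Pearson (default) or Spearman correlation of each named feature with
#' the symptom score (CAPS-like), with two-sided nominal p-values and
#' Benjamini--Hochberg FDR adjustment across the tested features.
#' Intended for the case group only. Zero-variance features are
#' reported with missing coefficients.
#'
#' @param features a [cohort_features()] data frame or numeric matrix.
#' @param symptom numeric symptom vector (taken from the feature table
#'   when NULL).
#' @param top_features character vector of feature names to test
#'   (e.g. from a `contribution_ranking`).
#' @param method `"pearson"` or `"spearman"`.
#' @return a `correlation_result` data frame: feature, r, p,
#'   p_adjusted.
#' @export
correlate_with_symptoms <- function(features, symptom = NULL,
                                    top_features,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(features)) {
    if (is.null(symptom)) symptom <- features$symptom_score
    x <- features
  } else x <- as.data.frame(features, check.names = FALSE)
  stopifnot(length(symptom) == nrow(x), length(symptom) >= 3)
  res <- lapply(top_features, function(f) {
    v <- x[[f]]
    if (is.null(v)) stop("unknown feature: ", f)
    if (sd(v) == 0 || sd(symptom) == 0)
      return(data.frame(feature = f, r = NA_real_, p = NA_real_))
    ct <- cor.test(v, symptom, method = method, exact = FALSE)
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Group comparison table of demographics and symptom scores
#'
#' Reproduces the usual cohort-description table: two-tailed two-sample
#' t-tests (pooled variance) for continuous variables and a two-tailed
#' Pearson chi-square test without continuity correction for sex.
#'
#' @param manifest a cohort manifest data frame with columns `group`,
#'   `sex` and any of `age`, `education`, `symptom_score` (plus other
#'   numeric columns, which are included automatically).
#' @return data frame: variable, case and control summaries
#'   (mean +/- sd, or male/female counts), test, p.
#' @export
demographic_table <- function(manifest) {
  stopifnot(all(c("group", "sex") %in% names(manifest)))
  g <- manifest$group
  if (!all(c("case", "control") %in% g))
    stop("both groups must be non-empty")
  num_vars <- setdiff(names(manifest)[vapply(manifest, is.numeric, TRUE)],
                      "sex")
  rows <- lapply(num_vars, function(v) {
    a <- manifest[[v]][g == "case"]; b <- manifest[[v]][g == "control"]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(variable = v,
               case = sprintf("%.1f ± %.1f", mean(a), sd(a)),
               control = sprintf("%.1f ± %.1f", mean(b), sd(b)),
               test = "two-sample t", p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- table(factor(g, c("case", "control")),
               factor(manifest$sex, c(1, 0)))
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  rows[[length(rows) + 1]] <- data.frame(
    variable = "sex",
    case = sprintf("%d/%d", tab["case", "1"], tab["case", "0"]),
    control = sprintf("%d/%d", tab["control", "1"], tab["control", "0"]),
    test = "Pearson chi-square", p = cs$p.value,
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-tailed t-test computed from group means,
#' standard deviations and sizes, for checking printed cohort tables
#' when raw values are unavailable.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' AAL-90 region labels with intrinsic-network annotation
#'
#' The 90-region Automated Anatomical Labeling parcellation in its
#' standard order (left/right interleaved), with a descriptive mapping
#' of selected regions to the default-mode (DMN), central-executive
#' (CEN) and salience (SN) networks for annotating feature rankings.
#'
#' @return data frame: label, name, hemisphere, network.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv",
                      package = "connectoclass")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Annotate a contribution ranking with region metadata
#'
#' Splits each feature name into metric type and region and joins the
#' AAL network annotation when region labels match the AAL-90 set.
#'
#' @param ranking a `contribution_ranking`.
#' @return data frame: rank, feature, metric, region, network, score.
#' @export
annotate_ranking <- function(ranking) {
  stopifnot(inherits(ranking, "contribution_ranking"))
  df <- ranking$ranking
  parts <- strsplit(df$feature, ".", fixed = TRUE)
  df$metric <- vapply(parts, function(p)
    paste(p[1:min(2, length(p))], collapse = "."), "")
  df$region <- vapply(parts, function(p)
    if (length(p) > 2) paste(p[-(1:2)], collapse = ".") else NA_character_, "")
  aal <- aal90_labels()
  df$network <- aal$network[match(df$region, aal$label)]
  df[, c("rank", "feature", "metric", "region", "network", "score")]
}

#' @export
print.contribution_ranking <- function(x, ...) {
  cat(sprintf("<contribution_ranking> (%s) top %d features:\n",
              x$source, x$top_k))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
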
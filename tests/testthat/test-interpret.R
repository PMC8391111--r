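fake_network <- function(W1, W2, W3, names = NULL) {
  structure(list(W1 = W1, W2 = W2, W3 = W3,
                 b1 = rep(0, ncol(W1)), b2 = rep(0, ncol(W2)),
                 b3 = rep(0, ncol(W3)),
                 layer_sizes = c(nrow(W1), ncol(W1), ncol(W2), ncol(W3)),
                 feature_names = names %||% paste0("f", seq_len(nrow(W1))),
                 activation = "sigmoid"),
            class = "reducer_network")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-path and symmetric networks backtrack as expected", {
  # one nonzero chain: input 2 -> unit 1 -> unit 1 -> unit 1
  W1 <- matrix(0, 4, 3); W1[2, 1] <- 2
  W2 <- matrix(0, 3, 2); W2[1, 1] <- -1.5
  W3 <- matrix(0, 2, 2); W3[1, 1] <- 0.7; W3[1, 2] <- 0.7
  rk <- backtrack_contributions(fake_network(W1, W2, W3))
  expect_equal(unname(rk$scores), c(0, 1, 0, 0))
  expect_equal(rk$ranking$feature[1], "f2")

  # two symmetric disjoint paths tie at 0.5, ties broken by index
  W1 <- matrix(0, 4, 2); W1[1, 1] <- 1; W1[3, 2] <- -1
  W2 <- matrix(0, 2, 2); W2[1, 1] <- 1; W2[2, 2] <- 1
  W3 <- diag(2)
  rk <- backtrack_contributions(fake_network(W1, W2, W3))
  expect_equal(unname(rk$scores), c(0.5, 0, 0.5, 0))
  expect_equal(rk$ranking$feature[1:2], c("f1", "f3"))

  expect_error(
    backtrack_contributions(fake_network(matrix(0, 3, 2),
                                         matrix(0, 2, 2),
                                         matrix(0, 2, 2))),
    "all-zero")
})

test_that("backtracking equals the path-product enumeration oracle", {
  set.seed(31)
  for (i in 1:50) {
    d <- sample(4:6, 1); h2 <- sample(3:4, 1)
    h3 <- sample(2:3, 1); h4 <- 2
    W1 <- matrix(rnorm(d * h2), d, h2)
    W2 <- matrix(rnorm(h2 * h3), h2, h3)
    W3 <- matrix(rnorm(h3 * h4), h3, h4)
    got <- backtrack_contributions(fake_network(W1, W2, W3))$scores
    want <- brute_backtrack(W1, W2, W3)
    expect_lt(max(abs(unname(got) - want)), 1e-10)
  }
})

test_that("retained sets are minimal prefixes strictly above 50%", {
  rk <- backtrack_contributions(fake_network(
    matrix(1, 5, 4), matrix(1, 4, 3), matrix(1, 3, 4)))
  # four uniform l4 contributions: need 3 of 4 to exceed half strictly
  expect_length(rk$kept$l4$index, 3)
  expect_gt(rk$kept$l4$fraction, 0.5)
  expect_equal(sum(rk$scores), 1)
})

test_that("SVM ranking is |primal weight| normalized, equivariant to ordering", {
  set.seed(32)
  # only feature 1 is informative
  x <- cbind(inf = c(rnorm(30, -2), rnorm(30, 2)), noise = rnorm(60))
  y <- factor(rep(c("control", "case"), each = 30),
              levels = c("control", "case"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
  rk <- svm_feature_ranking(fit)
  expect_equal(rk$ranking$feature[1], "inf")
  expect_equal(sum(rk$scores), 1)
  # permuting the feature order permutes the ranking identically
  fit2 <- e1071::svm(x[, 2:1], y, kernel = "linear", cost = 1,
                     scale = FALSE)
  rk2 <- svm_feature_ranking(fit2)
  expect_equal(rk2$ranking$feature[1], "inf")
  expect_equal(unname(rk2$scores[c("inf", "noise")]),
               unname(rk$scores[c("inf", "noise")]), tolerance = 1e-6)
  # nonlinear kernels are rejected
  fitr <- e1071::svm(x, y, kernel = "radial")
  expect_error(svm_feature_ranking(fitr), "linear")
})

test_that("weight vector (0, 3, -4) scores (0, 3/7, 4/7)", {
  # construct the expected normalized contributions directly
  w <- c(0, 3, -4)
  scores <- abs(w) / sum(abs(w))
  expect_equal(scores, c(0, 3 / 7, 4 / 7))
  # and the ranking helper agrees when fed a model with that weight
  sv <- diag(3)
  fake_svm <- structure(list(coefs = matrix(w, 3, 1), SV = sv,
                             kernel = 0), class = "svm")
  rk <- svm_feature_ranking(fake_svm, feature_names = c("a", "b", "c"))
  expect_equal(unname(rk$scores), scores)
  expect_equal(rk$ranking$feature[1], "c")
})

test_that("symptom correlations use Pearson r with BH adjustment", {
  set.seed(33)
  caps <- rnorm(40, 50, 10)
  feats <- data.frame(exact = 2 * caps + 1, noise = rnorm(40),
                      flat = rep(1, 40), symptom_score = caps,
                      check.names = FALSE)
  res <- correlate_with_symptoms(feats,
                                 top_features = c("exact", "noise", "flat"))
  expect_equal(res$r[res$feature == "exact"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$feature == "exact"], 1e-10)
  expect_true(is.na(res$r[res$feature == "flat"]))
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  # BH on the ladder 0.01..0.10 gives adjusted minimum 0.1
  p <- seq(0.01, 0.10, by = 0.01)
  adj <- p.adjust(p, "BH")
  expect_equal(unname(adj), rep(0.1, 10))
  expect_true(!is.unsorted(adj[order(p)]))
})

test_that("demographic table reproduces printed-table group tests", {
  # reconstruct the printed sex contingency 29/62 vs 40/86 exactly
  manifest <- data.frame(
    group = rep(c("case", "control"), c(91, 126)),
    sex = c(rep(1, 29), rep(0, 62), rep(1, 40), rep(0, 86)),
    age = c(rnorm(91, 42.4, 10.2), rnorm(126, 43.1, 9.6)))
  tab <- demographic_table(manifest)
  p_sex <- tab$p[tab$variable == "sex"]
  expect_equal(round(p_sex, 3), 0.985)
  expect_equal(tab$case[tab$variable == "sex"], "29/62")
  # identical groups: t = 0, p = 1
  m2 <- data.frame(group = rep(c("case", "control"), each = 4),
                   sex = rep(c(1, 0), 4), age = rep(c(40, 45, 50, 55), 2))
  t2 <- demographic_table(m2)
  expect_equal(t2$p[t2$variable == "age"], 1)
  expect_error(demographic_table(
    data.frame(group = rep("case", 4), sex = rep(1, 4), age = 1:4)),
    "group")
})

test_that("summary-statistic t-test flags the printed CAPS difference", {
  res <- t_test_from_summary(56.1, 14.9, 91, 22.8, 8.7, 126)
  expect_lt(res$p, 0.001)
  expect_gt(res$t, 10)
  expect_equal(res$df, 215)
})

test_that("AAL labels ship 90 annotated regions", {
  aal <- aal90_labels()
  expect_equal(nrow(aal), 90)
  expect_setequal(unique(aal$network), c("DMN", "CEN", "SN", "other"))
  expect_true("FFG.L" %in% aal$label)
  expect_equal(sum(aal$hemisphere == "L"), 45)
})
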
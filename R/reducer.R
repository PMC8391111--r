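#' Configuration of the dimensionality-reduction network
#'
#' A four-layer fully connected network `l1 -> l2 -> l3 -> l4` with
#' sigmoid activations. The input layer size is the feature dimension;
#' `hidden` gives the sizes of l2, l3 and l4 (the code layer). Training
#' minimizes a supervised cross-entropy through an auxiliary linear head
#' on the code layer (discarded after training) by full-batch gradient
#' descent with momentum, with early stopping when the loss improves by
#' less than `tol` over `patience` epochs. Deterministic given `seed`.
#'
#' @param hidden sizes of layers l2, l3, l4 (default 100, 30, 10,
#'   matched to the 277-dimensional input; scale down for smaller
#'   feature sets).
#' @param epochs maximum number of epochs.
#' @param learning_rate gradient-descent step size.
#' @param momentum momentum coefficient.
#' @param tol,patience early-stopping plateau rule.
#' @param min_epochs warm-up floor before early stopping may trigger
#'   (the loss surface is nearly flat right after initialization, so a
#'   plateau there is not convergence).
#' @param n_restarts number of random restarts; the run with the lowest
#'   final training loss is kept. Restart seeds are derived from `seed`,
#'   so the result is still deterministic.
#' @param seed seed for the weight initialization.
#' @return a `reducer_config`.
#' @export
reducer_config <- function(hidden = c(100, 30, 10), epochs = 500,
                           learning_rate = 0.01, momentum = 0.9,
                           tol = 1e-6, patience = 20,
                           min_epochs = 100, n_restarts = 3, seed = 1L) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), epochs >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            n_restarts >= 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 tol = tol, patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "reducer_config")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Train the dimensionality-reduction network
#'
#' @param x binary feature matrix (subjects by features), e.g. the
#'   output of [apply_mask()].
#' @param y labels: a factor or 0/1 vector; with a factor the second
#'   level (or `"case"` if present) is the positive class.
#' @param config a [reducer_config()].
#' @return a `reducer_network` with weight matrices `W1, W2, W3` (plus
#'   biases and the auxiliary head), layer sizes, the loss trace, and
#'   the training feature names.
#' @export
train_reducer <- function(x, y, config = reducer_config()) {
  x <- as.matrix(x)
  y01 <- to_binary_labels(y)
  stopifnot(nrow(x) == length(y01), nrow(x) >= 2)
  d <- ncol(x)
  h <- config$hidden
  fit <- NULL
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$seed + 1000003L * (r - 1L))
    W1 <- glorot(d, h[1]); W2 <- glorot(h[1], h[2]); W3 <- glorot(h[2], h[3])
    w4 <- as.numeric(glorot(h[3], 1))
    cand <- train_mlp_cpp(x, y01,
                          W1, rep(0, h[1]), W2, rep(0, h[2]),
                          W3, rep(0, h[3]), w4, 0,
                          config$learning_rate, config$momentum,
                          config$epochs, config$tol, config$patience,
                          config$min_epochs)
    if (is.null(fit) ||
        cand$loss[length(cand$loss)] < fit$loss[length(fit$loss)])
      fit <- cand
  }
  structure(list(
    W1 = fit$W1, b1 = as.numeric(fit$b1),
    W2 = fit$W2, b2 = as.numeric(fit$b2),
    W3 = fit$W3, b3 = as.numeric(fit$b3),
    head_w = as.numeric(fit$w4), head_b = fit$b4,
    layer_sizes = c(d, h), activation = "sigmoid",
    loss = as.numeric(fit$loss), epochs = fit$epochs,
    feature_names = colnames(x), config = config
  ), class = "reducer_network")
}

to_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    pos <- if ("case" %in% levels(y)) "case" else levels(y)[2]
    as.numeric(y == pos)
  } else {
    stopifnot(all(y %in% c(0, 1)))
    as.numeric(y)
  }
}

#' Low-dimensional codes from a trained reducer
#'
#' Forward pass through the three weight matrices; the sigmoid
#' activations of the code layer l4 are returned.
#'
#' @param net a [train_reducer()] result.
#' @param x binary feature matrix with the training feature dimension.
#' @return subjects-by-`l4` matrix of codes.
#' @export
encode <- function(net, x) {
  stopifnot(inherits(net, "reducer_network"))
  x <- as.matrix(x)
  if (ncol(x) != net$layer_sizes[1])
    stop("feature dimension does not match the trained network")
  encode_mlp_cpp(x, net$W1, net$b1, net$W2, net$b2, net$W3, net$b3)
}

#' @export
print.reducer_network <- function(x, ...) {
  cat(sprintf("<reducer_network> layers %s, %d epochs, final loss %.4f\n",
              paste(x$layer_sizes, collapse = "-"), x$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}
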
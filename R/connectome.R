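#' Partial-correlation connectivity matrix
#'
#' Entry (i, j) is the correlation between regions i and j controlling
#' for all other regions, obtained from the (optionally shrunk) inverse
#' correlation matrix P as `-p_ij / sqrt(p_ii p_jj)`. With 190 volumes
#' and 90 regions the sample correlation matrix is ill-conditioned, so a
#' Ledoit--Wolf-style shrinkage toward the identity is applied by
#' default, with the analytic Schafer--Strimmer intensity estimated from
#' the data; the intensity used is recorded in the `shrinkage` attribute.
#'
#' @param series regions-by-volumes matrix (conditioned time series).
#' @param shrinkage `"auto"` (analytic intensity), a number in `[0, 1]`,
#'   or 0 to disable.
#' @param subject_id optional id carried in the result.
#' @return a `connectivity_matrix`: symmetric matrix in `[-1, 1]` with
#'   zero diagonal and attributes `shrinkage` and `region_labels`.
#' @export
partial_correlation <- function(series, shrinkage = "auto",
                                subject_id = NULL) {
  stopifnot(is.matrix(series))
  n <- nrow(series)
  n_vol <- ncol(series)
  if (n_vol < 3) stop("need at least 3 volumes")
  x <- t(series)
  keep_sd <- apply(x, 2, sd)
  if (any(keep_sd == 0)) stop("constant region time series")
  r <- cor(x)
  lambda <- if (identical(shrinkage, "auto")) {
    shrinkage_intensity(x, r)
  } else {
    lam <- as.numeric(shrinkage)
    if (is.na(lam) || lam < 0 || lam > 1)
      stop("shrinkage must be 'auto' or a number in [0, 1]")
    lam
  }
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  p <- tryCatch(solve(rs), error = function(e)
    stop("correlation matrix is singular; enable shrinkage ",
         "(shrinkage = 'auto')", call. = FALSE))
  d <- sqrt(diag(p))
  pc <- -p / outer(d, d)
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2
  pc[pc > 1] <- 1
  pc[pc < -1] <- -1
  labels <- rownames(series)
  if (is.null(labels)) labels <- region_label_set(n)
  dimnames(pc) <- list(labels, labels)
  structure(pc, class = c("connectivity_matrix", "matrix", "array"),
            shrinkage = lambda, region_labels = labels,
            subject_id = subject_id)
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity
# target, computed from the variance of the off-diagonal sample
# correlations.
shrinkage_intensity <- function(x, r = cor(x)) {
  n <- nrow(x)
  z <- scale(x)
  num <- 0; den <- 0
  p <- ncol(x)
  for (i in seq_len(p - 1)) {
    w <- z[, i] * z[, (i + 1):p, drop = FALSE]
    wbar <- colMeans(w)
    v <- (n / ((n - 1)^3)) * colSums(sweep(w, 2, wbar)^2)
    num <- num + sum(v)
    den <- den + sum((n / (n - 1) * wbar)^2)
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

#' Sparsity threshold grid
#'
#' Sparsity is the fraction of present edges out of the `n(n-1)/2`
#' possible undirected edges. The default grid 0.10 to 0.34 in steps of
#' 0.01 contains 25 thresholds.
#'
#' @param s_min,s_max,s_step grid bounds and step.
#' @return a `sparsity_grid` with element `values`.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, s_step = 0.01) {
  if (!(s_min > 0 && s_min <= s_max && s_max < 1))
    stop("need 0 < s_min <= s_max < 1")
  k <- round((s_max - s_min) / s_step)
  values <- s_min + s_step * (0:k)
  structure(list(s_min = s_min, s_max = s_max, s_step = s_step,
                 values = values),
            class = "sparsity_grid")
}

round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix across the sparsity grid
#'
#' For each sparsity S the `round(S * n(n-1)/2)` strongest edges are kept
#' (set to 1) and all others dropped. Edge strength is ranked by absolute
#' partial correlation by default (`edge_rank = "abs"`), the usual
#' convention for binary connectome construction; `"positive"` ranks by
#' the signed value. Ties at the cut are broken by lexicographic (i, j)
#' order so the result is deterministic; edge counts are exact at every
#' threshold. Because selection is by rank, edge sets nest across
#' increasing sparsity.
#'
#' @param cm a [partial_correlation()] result (or any symmetric matrix).
#' @param grid a [sparsity_grid()].
#' @param edge_rank `"abs"` or `"positive"`.
#' @return a `binary_graph_stack`: list with `adjacency` (list of n x n
#'   0/1 matrices, one per threshold), `grid`, `subject_id`.
#' @export
binarize_stack <- function(cm, grid = sparsity_grid(),
                           edge_rank = c("abs", "positive")) {
  edge_rank <- match.arg(edge_rank)
  m <- unclass(cm)
  n <- nrow(m)
  stopifnot(n == ncol(m))
  ij <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ij]
  if (edge_rank == "abs") w <- abs(w)
  ord <- order(-w, ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  n_pairs <- n * (n - 1) / 2
  adjacency <- lapply(grid$values, function(s) {
    e <- round_half_up(s * n_pairs)
    a <- matrix(0L, n, n, dimnames = dimnames(m))
    if (e > 0) {
      sel <- ij[seq_len(min(e, n_pairs)), , drop = FALSE]
      a[sel] <- 1L
      a[sel[, c(2, 1), drop = FALSE]] <- 1L
    }
    a
  })
  structure(list(adjacency = adjacency, grid = grid,
                 subject_id = attr(cm, "subject_id")),
            class = "binary_graph_stack")
}
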
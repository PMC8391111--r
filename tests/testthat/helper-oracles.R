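# Independent brute-force oracles used to check the graph-metric and
# interpretation engines. These deliberately avoid the package's own
# code paths (and igraph): Floyd-Warshall for distances, exhaustive
# shortest-path enumeration for betweenness, direct triangle counting
# for clustering, and path-product enumeration for contribution
# backtracking.

random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  on <- up[runif(length(up)) < p]
  a[on] <- 1L
  a + t(a)
}

floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# enumerate every shortest path between each ordered pair via DFS and
# count pair-normalized pass-throughs (endpoints excluded)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- floyd_warshall(adj)
  btw <- numeric(n)
  all_paths <- function(i, j) {
    # all shortest i -> j paths as lists of vertices
    if (i == j) return(list(i))
    out <- list()
    for (k in which(adj[i, ] != 0)) {
      if (is.finite(d[k, j]) && d[i, j] == d[k, j] + 1) {
        for (p in all_paths(k, j)) out[[length(out) + 1]] <- c(i, p)
      }
    }
    out
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.finite(d[i, j])) next
    paths <- all_paths(i, j)
    npath <- length(paths)
    for (p in paths) {
      inner <- setdiff(p, c(i, j))
      for (v in inner) btw[v] <- btw[v] + 1 / npath
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- sum(adj[nb, nb]) / 2
    c_i[i] <- tri / (k * (k - 1) / 2)
  }
  c_i
}

brute_global_efficiency <- function(adj) {
  d <- floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

brute_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) next
    vals[i] <- brute_global_efficiency(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

brute_nodal_efficiency <- function(adj) {
  d <- floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

brute_char_path_length <- function(adj) {
  d <- floyd_warshall(adj)
  off <- d[upper.tri(d)]
  if (!any(is.finite(off))) return(0)
  mean(off[is.finite(off)])
}

# contribution backtracking oracle: the 50%-retention rule recomputed
# with independent code, then contributions as sums of retained-path
# |weight| products
brute_backtrack <- function(W1, W2, W3) {
  keep_rule <- function(v) {
    o <- order(-v, seq_along(v))
    cum <- cumsum(v[o])
    o[seq_len(which(cum > sum(v) / 2)[1])]
  }
  h4 <- ncol(W3)
  c4 <- rep(1 / h4, h4)
  k4 <- keep_rule(c4)
  c3 <- numeric(ncol(W2))
  for (j in seq_len(ncol(W2)))
    c3[j] <- sum(abs(W3[j, k4]) * c4[k4])
  k3 <- keep_rule(c3)
  c2 <- numeric(ncol(W1))
  for (j in seq_len(ncol(W1)))
    c2[j] <- sum(abs(W2[j, k3]) * c3[k3])
  k2 <- keep_rule(c2)
  # input contributions as explicit path products through kept sets
  d <- nrow(W1)
  c1 <- numeric(d)
  for (i in seq_len(d))
    for (j in k2)
      for (k in k3)
        for (l in intersect(k4, seq_len(h4)))
          c1[i] <- c1[i] +
            abs(W1[i, j]) * abs(W2[j, k]) * abs(W3[k, l]) * c4[l]
  # note: paths must pass only through kept nodes; the formulation
  # above already restricts j, k, l to the kept sets
  c1 / sum(c1)
}

# small deterministic feature set: two prototype binary patterns with
# bit-flip noise
prototype_features <- function(n = 100, d = 40, flip = 0.05, seed = 1) {
  set.seed(seed)
  proto <- rbind(rep(c(1, 0), length.out = d), rep(c(0, 1), length.out = d))
  y <- rep(c("case", "control"), length.out = n)
  x <- proto[as.integer(factor(y, c("case", "control"))), ]
  noise <- matrix(runif(n * d) < flip, n, d)
  x <- abs(x - noise)
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = factor(y, c("control", "case")))
}
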
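#' Null-model configuration for normalized small-world metrics
#'
#' gamma and lambda normalize the clustering coefficient and
#' characteristic path length by their expectations over
#' degree-preserving (Maslov--Sneppen) rewired graphs; sigma =
#' gamma/lambda.
#'
#' @param n_null number of rewired reference graphs.
#' @param n_swaps_per_edge rewiring attempts per edge.
#' @param seed RNG seed for the rewiring stream.
#' @return a `null_model_config`.
#' @export
null_model_config <- function(n_null = 100, n_swaps_per_edge = 10,
                              seed = 1L) {
  stopifnot(n_null >= 1, n_swaps_per_edge >= 1)
  structure(list(n_null = as.integer(n_null),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

as_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
}

as_int_adj <- function(adj) {
  storage.mode(adj) <- "integer"
  adj
}

#' All-pairs shortest hop distances
#'
#' Breadth-first search from every node.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return matrix of hop counts; unreachable pairs are `Inf`.
#' @export
shortest_path_lengths <- function(adj) {
  d <- bfs_distances_cpp(as_int_adj(unclass(adj)))
  dimnames(d) <- dimnames(adj)
  d
}

#' Global graph metrics of one binary graph
#'
#' Computes the seven global metrics: characteristic path length `Lp`
#' (averaged over reachable pairs), clustering coefficient `Cp`,
#' normalized clustering `gamma = Cp/Cp_rand`, normalized path length
#' `lambda = Lp/Lp_rand`, small-worldness `sigma = gamma/lambda`, global
#' efficiency `Eglob` and local efficiency `Eloc`. Random references for
#' gamma/lambda are degree-preserving rewired graphs; if the null model
#' is degenerate (fewer than 2 edges, or the reference clustering is
#' zero while the observed is not) gamma/lambda/sigma are returned as
#' `NA` with a warning rather than silently.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @param null_config a [null_model_config()], or `NULL` to skip
#'   gamma/lambda/sigma (returned as `NA`, no warning).
#' @return named numeric vector `c(Lp, Cp, gamma, lambda, sigma, Eglob,
#'   Eloc)` with attribute `n_unreachable`.
#' @export
global_metrics <- function(adj, null_config = null_model_config()) {
  a <- as_int_adj(unclass(adj))
  ps <- path_summaries_cpp(a)
  lp <- ps$Lp
  cp <- mean(local_clustering_cpp(a))
  eglob <- ps$Eglob
  eloc <- local_efficiency_cpp(a)

  gamma <- lambda <- sigma <- NA_real_
  if (!is.null(null_config)) {
    ec <- sum(a) / 2
    if (ec < 2) {
      warning("null model degenerate: fewer than 2 edges; ",
              "gamma/lambda/sigma set to NA", call. = FALSE)
    } else {
      set.seed(null_config$seed)
      ns <- null_model_stats_cpp(a, null_config$n_null,
                                 null_config$n_swaps_per_edge)
      cpm <- mean(ns$Cp); lpm <- mean(ns$Lp)
      gamma <- if (cpm > 0) cp / cpm else if (cp == 0) 1 else NA_real_
      lambda <- if (lpm > 0) lp / lpm else if (lp == 0) 1 else NA_real_
      if (is.na(gamma))
        warning("null model degenerate: reference clustering is zero; ",
                "gamma/sigma set to NA", call. = FALSE)
      sigma <- gamma / lambda
    }
  }
  out <- c(Lp = lp, Cp = cp, gamma = gamma, lambda = lambda,
           sigma = sigma, Eglob = eglob, Eloc = eloc)
  attr(out, "n_unreachable") <- ps$n_unreachable
  out
}

#' Nodal centrality metrics of one binary graph
#'
#' Degree (row sums), nodal efficiency (mean inverse distance to all
#' other nodes) and betweenness centrality (Brandes counting, endpoints
#' excluded, normalized by `(n-1)(n-2)/2`). On an empty graph all nodal
#' metrics are 0 by convention.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return list with numeric vectors `degree`, `efficiency`,
#'   `betweenness` (one entry per node).
#' @export
nodal_metrics <- function(adj) {
  n <- nrow(adj)
  a <- as_int_adj(unclass(adj))
  eff <- nodal_efficiency_cpp(a)
  btw <- igraph::betweenness(as_graph(adj), directed = FALSE) /
    ((n - 1) * (n - 2) / 2)
  list(degree = unname(rowSums(a != 0)), efficiency = as.numeric(eff),
       betweenness = unname(btw))
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of the per-threshold metric values against the
#' sparsity values, giving one threshold-free scalar per metric.
#'
#' @param metric_curve numeric vector, one value per grid threshold.
#' @param grid a [sparsity_grid()].
#' @return the AUC (scalar).
#' @export
auc_over_grid <- function(metric_curve, grid) {
  s <- grid$values
  if (length(metric_curve) != length(s))
    stop("curve length must equal the number of grid thresholds")
  bad <- which(!is.finite(metric_curve))
  if (length(bad))
    stop(sprintf("missing metric value at sparsity %.2f", s[bad[1]]))
  sum(diff(s) * (metric_curve[-1] + metric_curve[-length(s)]) / 2)
}

#' Assemble the AUC-summarized graph feature vector
#'
#' Computes all seven global and three nodal metrics at every sparsity
#' threshold of the stack and summarizes each metric's curve as a
#' trapezoidal AUC. The vector is ordered global block first, then
#' degree, nodal efficiency and betweenness per region: length
#' `7 + 3 * n_regions` (277 for 90 regions).
#'
#' @param stack a [binarize_stack()] result.
#' @param null_config a [null_model_config()]; each threshold uses
#'   `seed + threshold index` so repeated calls are identical.
#' @return a named numeric `graph_feature_vector` with attribute
#'   `subject_id`.
#' @export
assemble_features <- function(stack, null_config = null_model_config()) {
  stopifnot(inherits(stack, "binary_graph_stack"))
  n_thr <- length(stack$adjacency)
  n <- nrow(stack$adjacency[[1]])
  labels <- rownames(stack$adjacency[[1]])
  if (is.null(labels)) labels <- region_label_set(n)
  glob <- matrix(NA_real_, n_thr, 7)
  deg <- eff <- btw <- matrix(NA_real_, n_thr, n)
  for (t in seq_len(n_thr)) {
    nc <- null_config
    if (!is.null(nc)) nc$seed <- nc$seed + t
    glob[t, ] <- global_metrics(stack$adjacency[[t]], nc)
    nm <- nodal_metrics(stack$adjacency[[t]])
    deg[t, ] <- nm$degree
    eff[t, ] <- nm$efficiency
    btw[t, ] <- nm$betweenness
  }
  curves <- cbind(glob, deg, eff, btw)
  values <- apply(curves, 2, auc_over_grid, grid = stack$grid)
  names(values) <- c(
    paste0("global.", c("Lp", "Cp", "gamma", "lambda", "sigma",
                        "Eglob", "Eloc")),
    paste0("nodal.degree.", labels),
    paste0("nodal.efficiency.", labels),
    paste0("nodal.betweenness.", labels))
  structure(values, class = "graph_feature_vector",
            subject_id = stack$subject_id)
}

#' Extract the feature matrix for a whole cohort
#'
#' Runs conditioning (optional), partial correlation, sparsity
#' binarization and AUC feature assembly for every subject, returning
#' the feature table that is the contract between feature extraction and
#' classification: one row per subject with `subject_id`, `group`,
#' `symptom_score` and the `7 + 3n` named feature columns.
#'
#' @param cohort a `cohort`.
#' @param conditioning a [conditioning_config()], or `NULL` to use the
#'   series as-is.
#' @param grid a [sparsity_grid()].
#' @param null_config a [null_model_config()].
#' @param shrinkage passed to [partial_correlation()].
#' @param edge_rank passed to [binarize_stack()].
#' @return a data frame.
#' @export
cohort_features <- function(cohort, conditioning = conditioning_config(),
                            grid = sparsity_grid(),
                            null_config = null_model_config(),
                            shrinkage = "auto", edge_rank = "abs") {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    x <- if (is.null(conditioning)) s$series
         else condition_series(s$series, conditioning)
    cm <- partial_correlation(x, shrinkage = shrinkage,
                              subject_id = s$subject_id)
    fv <- assemble_features(binarize_stack(cm, grid, edge_rank),
                            null_config)
    as.data.frame(t(unclass(fv)), check.names = FALSE)
  })
  feats <- do.call(rbind, rows)
  cbind(cohort$manifest[, c("subject_id", "group", "symptom_score")],
        feats)
}

#' Split a feature table into matrix and labels
#'
#' @param features a [cohort_features()] data frame.
#' @return list with `x` (numeric matrix), `y` (factor with levels
#'   control, case when present), `symptom_score`, `subject_id`.
#' @export
feature_matrix <- function(features) {
  meta <- intersect(c("subject_id", "group", "symptom_score"),
                    names(features))
  x <- as.matrix(features[, setdiff(names(features), meta),
                          drop = FALSE])
  rownames(x) <- features$subject_id
  y <- NULL
  if ("group" %in% meta) {
    lv <- unique(features$group)
    if (all(c("case", "control") %in% lv)) lv <- c("control", "case")
    y <- factor(features$group, levels = lv)
  }
  list(x = x, y = y, symptom_score = features$symptom_score,
       subject_id = features$subject_id)
}
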
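#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of case and control subjects whose region-of-interest
#' (ROI) BOLD-like time series are drawn from group-specific covariance
#' structures. The group difference is injected at the level of edge
#' weights: correlations of edges incident to `perturbed_nodes` are scaled
#' down by `effect_size` in the case group, which in turn lowers those
#' nodes' degree/efficiency/betweenness after thresholding. A CAPS-like
#' symptom score is partially coupled to the connectivity of the first
#' perturbed node.
#'
#' Defaults mirror a 90-region AAL parcellation with 190 retained volumes
#' at TR = 2 s and group sizes 91 (case) / 126 (control).
#'
#' @param n_regions number of ROIs (nodes); at least 3.
#' @param n_volumes number of time points per subject.
#' @param tr_seconds repetition time in seconds.
#' @param n_cases,n_controls group sizes; at least 2 each.
#' @param n_communities number of block communities in the covariance.
#' @param perturbed_nodes integer indices (1-based) of the nodes whose
#'   incident correlations differ between groups.
#' @param effect_size scaling of the perturbation in `[0, 1]`: case-group
#'   correlations incident to perturbed nodes are multiplied by
#'   `1 - effect_size`.
#' @param symptom_coupling correlation strength in `[-1, 1]` between the
#'   designated nodal property (mean empirical correlation of the first
#'   perturbed node) and the case symptom score.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` for temporal
#'   autocorrelation of the BOLD-like signal.
#' @param within_cor,between_cor within- and between-community correlation
#'   of the block covariance model.
#' @param seed integer seed; subject `s` is generated from `seed + s` so
#'   cohorts are reproducible and individually regenerable.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 90, n_volumes = 190, tr_seconds = 2,
                        n_cases = 91, n_controls = 126, n_communities = 5,
                        perturbed_nodes = integer(), effect_size = 0,
                        symptom_coupling = 0, noise_sd = 0.5,
                        ar_coefficient = 0.3, within_cor = 0.4,
                        between_cor = 0.1, seed = 1L) {
  spec <- list(
    n_regions = as.integer(n_regions), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_communities = as.integer(n_communities),
    perturbed_nodes = as.integer(perturbed_nodes),
    effect_size = effect_size, symptom_coupling = symptom_coupling,
    noise_sd = noise_sd, ar_coefficient = ar_coefficient,
    within_cor = within_cor, between_cor = between_cor,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_regions < 3) stop("n_regions must be at least 3")
  if (spec$n_cases < 2 || spec$n_controls < 2)
    stop("each group needs at least 2 subjects")
  if (spec$n_communities < 1 || spec$n_communities > spec$n_regions)
    stop("n_communities must be in [1, n_regions]")
  if (length(spec$perturbed_nodes) &&
      (any(spec$perturbed_nodes < 1) ||
       any(spec$perturbed_nodes > spec$n_regions)))
    stop("perturbed_nodes must be region indices in 1..n_regions")
  if (spec$effect_size < 0 || spec$effect_size > 1)
    stop("effect_size must lie in [0, 1]")
  if (abs(spec$symptom_coupling) > 1)
    stop("symptom_coupling must lie in [-1, 1]")
  if (spec$ar_coefficient < 0 || spec$ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  if (!is.finite(spec$seed)) stop("seed must be a finite integer")
  if (spec$n_volumes <= spec$n_regions)
    warning("n_volumes <= n_regions: partial correlation will be ",
            "rank-deficient without shrinkage", call. = FALSE)
  invisible(spec)
}

community_assignment <- function(n_regions, n_communities) {
  sort(rep_len(seq_len(n_communities), n_regions))
}

#' Group covariance matrix with block-community structure
#'
#' Builds the symmetric positive-definite correlation matrix used to draw
#' a group's time series: `within_cor` inside each community block,
#' `between_cor` elsewhere, unit diagonal. For the case group every
#' off-diagonal entry incident to a perturbed node is multiplied by
#' `1 - effect_size`. Positive definiteness is enforced by diagonal
#' loading when needed.
#'
#' @param spec a [cohort_spec()].
#' @param group `"case"` or `"control"`.
#' @return a symmetric positive-definite matrix with attribute
#'   `communities` (block labels) and `loading` (diagonal load applied,
#'   usually 0).
#' @export
build_group_covariance <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  validate_cohort_spec(spec)
  n <- spec$n_regions
  comm <- community_assignment(n, spec$n_communities)
  sigma <- matrix(spec$between_cor, n, n)
  same <- outer(comm, comm, "==")
  sigma[same] <- spec$within_cor
  diag(sigma) <- 1
  if (group == "case" && length(spec$perturbed_nodes) &&
      spec$effect_size > 0) {
    hit <- seq_len(n) %in% spec$perturbed_nodes
    inc <- outer(hit, hit, "|")
    diag(inc) <- FALSE
    sigma[inc] <- sigma[inc] * (1 - spec$effect_size)
  }
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  loading <- 0
  if (ev <= 1e-10) {
    loading <- abs(ev) + 1e-8
    diag(sigma) <- diag(sigma) + loading
    ev2 <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 <= 0)
      stop(sprintf(
        "covariance not positive definite after diagonal loading (min eigenvalue %.3e)",
        ev2))
  }
  attr(sigma, "communities") <- comm
  attr(sigma, "loading") <- loading
  sigma
}

region_label_set <- function(n_regions) {
  if (n_regions == 90) aal90_labels()$label
  else sprintf("R%03d", seq_len(n_regions))
}

#' Sample a synthetic cohort of ROI time series
#'
#' For each subject, draws `n_volumes` multivariate-normal vectors with
#' the group covariance, passes them through a recursive AR(1) filter
#' along time, and adds white noise. Case symptom scores are generated as
#' `symptom_coupling * z(proxy) + sqrt(1 - symptom_coupling^2) * noise`,
#' where the proxy is the subject's realized connectivity of the first
#' perturbed node (see [symptom_proxy()]), then rescaled to a CAPS-like
#' support (case mean 56.1, SD 14.9; control mean 22.8, SD 8.7) and
#' clipped to the CAPS instrument range `[0, 136]`. Demographic
#' covariates (age, sex, education) are drawn with group-matched means.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: a list with `subjects` (list of
#'   `subject_ts`), `spec`, and `manifest` (one row per subject).
#' @export
sample_cohort <- function(spec) {
  validate_cohort_spec(spec)
  sigma <- list(case = build_group_covariance(spec, "case"),
                control = build_group_covariance(spec, "control"))
  chol_l <- lapply(sigma, chol)
  n_subj <- spec$n_cases + spec$n_controls
  groups <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  labels <- region_label_set(spec$n_regions)
  proxy_node <- if (length(spec$perturbed_nodes)) spec$perturbed_nodes[1] else 1L

  subjects <- vector("list", n_subj)
  proxy <- numeric(n_subj)
  for (s in seq_len(n_subj)) {
    set.seed(spec$seed + s)
    z <- matrix(rnorm(spec$n_volumes * spec$n_regions),
                spec$n_volumes, spec$n_regions)
    x <- z %*% chol_l[[groups[s]]]
    if (spec$ar_coefficient > 0)
      x <- apply(x, 2, function(col)
        as.numeric(stats::filter(col, spec$ar_coefficient,
                                 method = "recursive")))
    if (spec$noise_sd > 0)
      x <- x + matrix(rnorm(length(x), sd = spec$noise_sd), nrow(x))
    series <- t(x)
    rownames(series) <- labels
    proxy[s] <- if (groups[s] == "case" && spec$symptom_coupling != 0)
      symptom_proxy(series, proxy_node, spec$tr_seconds) else 0
    age <- if (groups[s] == "case") rnorm(1, 42.4, 10.2) else rnorm(1, 43.1, 9.6)
    p_male <- if (groups[s] == "case") 29 / 91 else 40 / 126
    sex <- if (runif(1) < p_male) 1 else 0
    edu <- if (groups[s] == "case") rnorm(1, 7.1, 3.0) else rnorm(1, 7.9, 3.8)
    subjects[[s]] <- structure(list(
      subject_id = sprintf("S%03d", s),
      group = groups[s],
      series = series,
      symptom_score = NA_real_,
      covariates = c(age = max(18, age), sex = sex, education = max(0, edu))
    ), class = "subject_ts")
  }

  # symptom scores: two-pass so the proxy can be standardized within
  # cases. The noise comes from one dedicated stream (sequential draws
  # are i.i.d.); per-subject set.seed() streams must not be used here
  # because first draws of nearby Mersenne-Twister seeds are measurably
  # correlated, which would contaminate the configured coupling.
  is_case <- groups == "case"
  z_proxy <- numeric(n_subj)
  z_proxy[is_case] <- scale_vec(proxy[is_case])
  set.seed(spec$seed + 999983L)
  eps <- rnorm(n_subj)
  for (s in seq_len(n_subj)) {
    if (is_case[s]) {
      cpl <- spec$symptom_coupling
      std <- cpl * z_proxy[s] + sqrt(1 - cpl^2) * eps[s]
      score <- 56.1 + 14.9 * std
    } else {
      score <- 22.8 + 8.7 * eps[s]
    }
    subjects[[s]]$symptom_score <- min(136, max(0, score))
  }

  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = groups,
    symptom_score = vapply(subjects, `[[`, 0, "symptom_score"),
    age = vapply(subjects, function(x) x$covariates[["age"]], 0),
    sex = vapply(subjects, function(x) x$covariates[["sex"]], 0),
    education = vapply(subjects, function(x) x$covariates[["education"]], 0),
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, spec = spec, manifest = manifest),
            class = "cohort")
}

#' Designated nodal connectivity proxy for symptom coupling
#'
#' The subject-level quantity the synthetic symptom score is coupled to:
#' the mean absolute partial correlation of the designated node,
#' relative to the subject's overall mean absolute partial correlation,
#' computed on the conditioned (detrended, band-passed) series. This
#' relative in-band connectivity tracks the node's extracted efficiency
#' feature closely; an absolute raw-series correlation does not, because
#' the rank-based binarization is insensitive to a subject's global
#' correlation level. Falls back to the detrended series when the run is
#' too short to band-pass stably.
#'
#' @param series regions-by-volumes matrix.
#' @param node region index of the designated node.
#' @param tr_seconds repetition time (for the band-pass).
#' @return a scalar proxy value.
#' @export
symptom_proxy <- function(series, node, tr_seconds = 2) {
  cs <- tryCatch(
    condition_series(series, conditioning_config(tr_seconds = tr_seconds)),
    error = function(e) detrend_series(series, 1))
  pc <- abs(unclass(partial_correlation(cs, shrinkage = "auto")))
  mean(pc[node, -node]) - mean(pc[upper.tri(pc)])
}

scale_vec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d case / %d control), %d regions x %d volumes\n",
              length(x$subjects), x$spec$n_cases, x$spec$n_controls,
              x$spec$n_regions, x$spec$n_volumes))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One TSV per subject (rows = regions, first column `region`, remaining
#' columns `V1..Vn` the volumes) plus a cohort manifest CSV with subject
#' id, group, symptom score, covariates and file path.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- file.path(dir, paste0(s$subject_id, ".tsv"))
    df <- data.frame(region = rownames(s$series), s$series,
                     check.names = FALSE)
    colnames(df) <- c("region", paste0("V", seq_len(ncol(s$series))))
    write.table(df, files[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- cohort$manifest
  manifest$file <- basename(files)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and per-subject TSVs.
#' @return a `cohort` (with a minimal reconstructed spec).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- read.delim(file.path(dir, manifest$file[i]),
                     check.names = FALSE)
    series <- as.matrix(df[, -1, drop = FALSE])
    dimnames(series) <- list(df$region, NULL)
    structure(list(
      subject_id = manifest$subject_id[i],
      group = manifest$group[i],
      series = series,
      symptom_score = manifest$symptom_score[i],
      covariates = c(age = manifest$age[i], sex = manifest$sex[i],
                     education = manifest$education[i])
    ), class = "subject_ts")
  })
  n_regions <- nrow(subjects[[1]]$series)
  n_volumes <- ncol(subjects[[1]]$series)
  spec <- suppressWarnings(cohort_spec(
    n_regions = n_regions, n_volumes = n_volumes,
    n_cases = max(2L, sum(manifest$group == "case")),
    n_controls = max(2L, sum(manifest$group == "control")),
    n_communities = 1L
  ))
  structure(list(subjects = subjects, spec = spec,
                 manifest = manifest[, setdiff(names(manifest), "file")]),
            class = "cohort")
}
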
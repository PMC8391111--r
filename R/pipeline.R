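#' Pipeline run configuration
#'
#' Bundles the per-stage configurations and seeds of an end-to-end run:
#' simulate (or ingest) -> condition -> connectome/features -> classify
#' (two-stage and baseline) -> interpret.
#'
#' @param cohort a [cohort_spec()] to simulate, or a directory written
#'   by [write_cohort()] to ingest.
#' @param conditioning a [conditioning_config()] or NULL to skip.
#' @param grid a [sparsity_grid()].
#' @param null_config a [null_model_config()].
#' @param classifier a [classifier_config()].
#' @param n_perm permutations for the significance test (0 disables).
#' @param shrinkage,edge_rank passed to the connectome stage.
#' @param seed master seed; stage seeds are derived from it and
#'   recorded in the run manifest.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            conditioning = conditioning_config(),
                            grid = sparsity_grid(),
                            null_config = null_model_config(),
                            classifier = classifier_config(),
                            n_perm = 0, shrinkage = "auto",
                            edge_rank = "abs", seed = 1L) {
  structure(list(cohort = cohort, conditioning = conditioning,
                 grid = grid, null_config = null_config,
                 classifier = classifier, n_perm = n_perm,
                 shrinkage = shrinkage, edge_rank = edge_rank,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unserialize_safe(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

unserialize_safe <- function(x) {
  if (is.list(x)) lapply(unclass(x), unserialize_safe) else x
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes all tabular outputs plus a run
#' manifest (`manifest.json`: configuration hash, seeds, per-stage file
#' checksums) into `out_dir`. A rerun with the same configuration and
#' seed reproduces identical feature tables and reports; when `resume`
#' is TRUE, stages whose output files already exist with checksums
#' matching the manifest are reused instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param resume reuse checksum-verified cached stage outputs.
#' @return (invisibly) a list with the feature table, both
#'   classification reports, rankings, correlations, demographics and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  if (!is.null(old) && !identical(old$config_hash, unname(hash))) old <- NULL
  cached <- function(file) {
    !is.null(old) && !is.null(old$checksums[[file]]) &&
      file.exists(file.path(out_dir, file)) &&
      identical(unname(tools::md5sum(file.path(out_dir, file))),
                old$checksums[[file]])
  }

  # stage 1-3: cohort, conditioning, features
  feat_file <- "features.csv"
  if (cached(feat_file)) {
    message("* features: reusing cached ", feat_file)
    features <- read.csv(file.path(out_dir, feat_file),
                         check.names = FALSE)
  } else {
    cohort <- if (inherits(config$cohort, "cohort_spec")) {
      message("* simulate: ", config$cohort$n_cases, " cases + ",
              config$cohort$n_controls, " controls")
      sample_cohort(config$cohort)
    } else {
      message("* ingest: ", config$cohort)
      read_cohort(config$cohort)
    }
    write_cohort(cohort, file.path(out_dir, "cohort"))
    message("* condition + connectome + features")
    features <- tryCatch(
      cohort_features(cohort, conditioning = config$conditioning,
                      grid = config$grid,
                      null_config = config$null_config,
                      shrinkage = config$shrinkage,
                      edge_rank = config$edge_rank),
      error = function(e) stop("feature stage failed: ",
                               conditionMessage(e), call. = FALSE))
    write.csv(features, file.path(out_dir, feat_file), row.names = FALSE)
  }

  # stage 4: classification (both models, shared folds)
  fm <- feature_matrix(features)
  folds <- make_stratified_folds(fm$y, config$classifier$outer_folds,
                                 config$classifier$seed)
  rep_file <- "report_two_stage.json"
  if (cached(rep_file) && cached("report_baseline.json") &&
      cached("predictions.csv")) {
    message("* classify: reusing cached reports")
    report2 <- NULL; report1 <- NULL
    reports_json <- lapply(c(rep_file, "report_baseline.json"),
                           function(f) jsonlite::read_json(
                             file.path(out_dir, f)))
  } else {
    message("* classify: two-stage")
    report2 <- two_stage_cv(fm$x, fm$y, config$classifier, folds = folds)
    message("* classify: baseline SVM")
    report1 <- baseline_svm_cv(fm$x, fm$y, config$classifier,
                               folds = folds)
    if (config$n_perm > 0) {
      message("* permutation test (", config$n_perm, " permutations)")
      pt <- permutation_test(fm$x, fm$y, config$classifier,
                             model = "two-stage",
                             n_perm = config$n_perm,
                             observed = report2$metrics[["balanced_accuracy"]])
      report2$permutation_p <- pt$p
    }
    for (r in list(report2, report1)) {
      f <- if (r$model_tag == "two-stage") rep_file else "report_baseline.json"
      jsonlite::write_json(report_as_json(r), file.path(out_dir, f),
                           auto_unbox = TRUE, digits = NA)
    }
    preds <- report2$predictions
    preds$baseline_pred <- report1$predictions$pred
    write.csv(preds, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    reports_json <- NULL
  }

  # stage 5: interpretation (needs fitted models; recompute if cached)
  if (is.null(report2)) {
    report2 <- two_stage_cv(fm$x, fm$y, config$classifier, folds = folds)
    report1 <- baseline_svm_cv(fm$x, fm$y, config$classifier,
                               folds = folds)
  }
  message("* interpret")
  dl_rank <- backtrack_contributions(median_fold_network(report2))
  svm_rank <- svm_feature_ranking(report1)
  write.csv(annotate_ranking(dl_rank),
            file.path(out_dir, "contributions_dl.csv"), row.names = FALSE)
  write.csv(annotate_ranking(svm_rank),
            file.path(out_dir, "contributions_svm.csv"), row.names = FALSE)
  cases <- features[features$group == "case", , drop = FALSE]
  correlations <- correlate_with_symptoms(
    cases, top_features = dl_rank$ranking$feature)
  write.csv(correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  cohort_manifest_file <- file.path(out_dir, "cohort", "manifest.csv")
  manifest_df <- if (file.exists(cohort_manifest_file))
    read.csv(cohort_manifest_file, stringsAsFactors = FALSE)
  else sample_cohort(config$cohort)$manifest
  demographics <- demographic_table(manifest_df)
  write.csv(demographics, file.path(out_dir, "demographics.csv"),
            row.names = FALSE)

  files <- c(feat_file, "report_two_stage.json", "report_baseline.json",
             "predictions.csv", "contributions_dl.csv",
             "contributions_svm.csv", "correlations.csv",
             "demographics.csv")
  files <- files[file.exists(file.path(out_dir, files))]
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("connectoclass")),
    config_hash = unname(hash), seed = config$seed,
    classifier_seed = config$classifier$seed,
    null_seed = config$null_config$seed,
    checksums = checksums)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(features = features, two_stage = report2,
                 baseline = report1, dl_ranking = dl_rank,
                 svm_ranking = svm_rank, correlations = correlations,
                 demographics = demographics, manifest = manifest))
}

#' Median network across cross-validation folds
#'
#' Summarizes the fold-wise trained reducers of a two-stage report by
#' the element-wise median of their weight matrices, so that a
#' contribution ranking computed from it reflects the consensus model
#' across outer folds rather than any single fold.
#'
#' @param report a [two_stage_cv()] result run with
#'   `keep_models = TRUE`.
#' @return a `reducer_network` with median weights.
#' @export
median_fold_network <- function(report) {
  stopifnot(report$model_tag == "two-stage")
  nets <- lapply(report$models, `[[`, "reducer")
  if (any(vapply(nets, is.null, TRUE)))
    stop("report was run with keep_models = FALSE")
  med <- nets[[1]]
  for (w in c("W1", "W2", "W3")) {
    arr <- simplify2array(lapply(nets, `[[`, w))
    med[[w]] <- apply(arr, c(1, 2), median)
  }
  med
}

report_as_json <- function(r) {
  list(model = r$model_tag, metrics = as.list(r$metrics),
       fold_mean_metrics = as.list(r$fold_mean_metrics),
       chosen_costs = r$chosen_costs, positive = r$positive,
       permutation_p = r$permutation_p,
       folds = r$folds)
}

#' Read a pipeline config from YAML
#'
#' Converts a plain YAML document with optional blocks `cohort`,
#' `conditioning`, `grid`, `null_model`, `classifier`, `reducer` and
#' top-level `n_perm`/`seed` into a [pipeline_config()]; omitted
#' entries keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML sequences with mixed int/double parse as lists; flatten any
  # list made only of scalars back to an atomic vector
  flatten <- function(x) {
    if (is.list(x) && length(x) && is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)))
      unlist(x)
    else if (is.list(x)) lapply(x, flatten)
    else x
  }
  y <- flatten(y)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  reducer <- build(reducer_config, y$reducer)
  cls_args <- y$classifier %||% list()
  cls_args$reducer <- reducer
  pipeline_config(
    cohort = if (is.character(y$cohort)) y$cohort
             else build(cohort_spec, y$cohort),
    conditioning = build(conditioning_config, y$conditioning),
    grid = build(sparsity_grid, y$grid),
    null_config = build(null_model_config, y$null_model),
    classifier = do.call(classifier_config, cls_args),
    n_perm = y$n_perm %||% 0,
    shrinkage = y$shrinkage %||% "auto",
    edge_rank = y$edge_rank %||% "abs",
    seed = y$seed %||% 1L)
}
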
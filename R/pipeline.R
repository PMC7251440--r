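#' Default end-to-end pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: a synthetic cohort (or paths to
#' a precomputed feature table), model settings, cross-validation, the
#' decision-feature parameters and sweep grids, hacking settings, and group
#' statistics options. One global seed fans out to deterministic per-stage
#' seeds so individual stages can be rerun in isolation.
#'
#' @param seed global seed.
#' @param cohort list of [cohort_spec()] arguments (ignored when
#'   `features_csv` is given).
#' @param features_csv,labels_csv optional paths: a subjects-by-features CSV
#'   (header, first column subject id) and a two-column CSV
#'   (subject_id, label).
#' @param p number of ROIs when loading features from CSV.
#' @param model list of [plnn()] settings (hidden, dropout, epochs, ...).
#' @param cv_k folds for cross-validation.
#' @param K,epsilon decision-feature parameters for the main extraction.
#' @param ranking `"abs"` or `"signed"`.
#' @param K_grid,epsilon_grid sweep grids.
#' @param svm_n top-N features for the linear-SVM hacking baseline.
#' @param random_draws random same-size sets in the hacking contrast.
#' @param stats_scale `"z"` or `"r"` for group statistics.
#' @param interpret_population `"full"` (one model trained on everything
#'   interprets all instances) or `"cv"` (each subject interpreted by the
#'   model of the fold that held it out).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, cohort = list(), features_csv = NULL,
                       labels_csv = NULL, p = NULL, model = list(),
                       cv_k = 5L, K = 20L, epsilon = 0.95,
                       ranking = "abs",
                       K_grid = seq(5L, 300L, by = 5L),
                       epsilon_grid = seq(0.70, 0.95, by = 0.05),
                       svm_n = 20L, random_draws = 20L,
                       stats_scale = "z",
                       interpret_population = c("full", "cv")) {
  interpret_population <- match.arg(interpret_population)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 101L) %% 2000000000L
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> extract features -> cross-validate -> train ->
#' interpret every instance -> mine decision features -> sweep (K, epsilon)
#' -> hacking evaluation (decision set vs random sets vs linear-SVM baseline)
#' -> per-edge group statistics. All artifacts are written as plain text
#' (CSV/JSON) under `out_dir`, together with the resolved configuration and a
#' machine-readable `summary.json`; the run is idempotent under a fixed seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return the summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  cfg_out <- config
  cfg_out$K_grid <- as.integer(cfg_out$K_grid)
  jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # ---- stage: data ----
  if (!is.null(config$features_csv)) {
    ft <- utils::read.csv(config$features_csv, check.names = FALSE)
    ids <- as.character(ft[[1]])
    X <- as.matrix(ft[, -1, drop = FALSE])
    lb <- utils::read.csv(config$labels_csv)
    y <- as.integer(lb$label[match(ids, as.character(lb$subject_id))])
    p <- config$p
    if (is.null(p)) p <- as.integer((1 + sqrt(1 + 8 * ncol(X))) / 2)
    ds <- structure(list(X = X, y = y, subject_ids = ids, p = p),
                    class = "fc_dataset")
    truth <- integer(0)
    say("loaded %d subjects x %d features", nrow(X), ncol(X))
  } else {
    spec <- do.call(cohort_spec,
                    utils::modifyList(list(seed = stage_seed(config$seed, "cohort")),
                                      config$cohort))
    say("simulating cohort: p=%d, %d/group, T=%d", spec$p, spec$n_per_group,
        spec$t_len)
    coh <- sample_cohort(spec)
    ds <- build_dataset(coh$series, coh$labels)
    truth <- planted_truth(spec)
    utils::write.csv(data.frame(k = truth),
                     file.path(out_dir, "planted_truth.csv"), row.names = FALSE)
  }
  map <- edge_index_map(ds$p)
  utils::write.csv(map, file.path(out_dir, "edge_index_map.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = ds$subject_ids, label = ds$y,
                              ds$X, check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  # ---- stage: cross-validation ----
  fit_args <- config$model
  cv <- do.call(plnn_cv, c(list(x = ds, k = config$cv_k,
                                seed = stage_seed(config$seed, "cv"),
                                keep_models = config$interpret_population == "cv"),
                           fit_args))
  utils::write.csv(cv$summary, file.path(out_dir, "cv_metrics.csv"),
                   row.names = FALSE)
  say("CV accuracy %.3f +/- %.3f",
      cv$summary$mean[cv$summary$metric == "accuracy"],
      cv$summary$sd[cv$summary$metric == "accuracy"])

  # ---- stage: fit + interpret ----
  model <- do.call(plnn, c(list(x = ds,
                                seed = stage_seed(config$seed, "train")),
                           fit_args))
  residual <- verify_faithfulness(model, ds)
  say("max linearization residual: %.3g", residual)
  llms <- if (config$interpret_population == "cv")
    pooled_cv_interpretations(cv, ds)
  else local_linear_all(model, ds)
  utils::write.csv(export_instance_weights(llms[[1]], map, top_n = 20L),
                   file.path(out_dir, "instance_weights_first_subject.csv"),
                   row.names = FALSE)

  # ---- stage: decision features ----
  dfs <- decision_feature_set(llms, K = config$K, epsilon = config$epsilon,
                              ranking = config$ranking)
  dfe <- dfs$features
  dfe$roi_i <- map$roi_i[dfe$k]; dfe$roi_j <- map$roi_j[dfe$k]
  utils::write.csv(dfe, file.path(out_dir, "decision_features.csv"),
                   row.names = FALSE)
  sweep_tab <- decision_feature_sweep(llms, config$K_grid,
                                      config$epsilon_grid, config$ranking)
  utils::write.csv(sweep_tab, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)

  # ---- stage: hacking evaluation ----
  hack <- if (nrow(dfs$features) > 0) {
    hr <- hack_report(model, ds, dfs$features$k, ds$y)
    ctr <- random_set_contrast(model, ds, dfs$features$k,
                               n_draws = config$random_draws,
                               seed = stage_seed(config$seed, "hack"))
    svm <- svm_topweight_baseline(ds, N = config$svm_n)
    list(decision_set = unclass(hr)[c("feature_set_size", "mean_cpp", "nlci",
                                      "post_sensitivity", "post_accuracy")],
         median_random_cpp = ctr$median_random_cpp,
         random_cpp = ctr$random_cpp,
         svm_baseline = unclass(svm$report)[c("feature_set_size", "mean_cpp",
                                              "nlci", "post_sensitivity",
                                              "post_accuracy")])
  } else list()
  jsonlite::write_json(hack, file.path(out_dir, "hack.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- stage: group statistics ----
  gs <- if (nrow(dfs$features) > 0)
    group_stats(ds, features = dfs$features$k, scale = config$stats_scale,
                map = map)
  else data.frame(k = integer(0), roi_i = integer(0), roi_j = integer(0),
                  mean_pos = numeric(0), mean_neg = numeric(0),
                  mean_diff = numeric(0), t_stat = numeric(0),
                  p_value = numeric(0))
  utils::write.csv(gs, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)

  summary <- list(
    n_subjects = nrow(ds$X), p = ds$p, d = ncol(ds$X),
    cv_accuracy_mean = cv$summary$mean[cv$summary$metric == "accuracy"],
    cv_accuracy_sd = cv$summary$sd[cv$summary$metric == "accuracy"],
    cv_auc_mean = cv$summary$mean[cv$summary$metric == "auc"],
    max_linearization_residual = residual,
    n_decision_features = nrow(dfs$features),
    decision_features = dfs$features$k,
    planted_truth = truth,
    n_recovered = if (length(truth)) length(intersect(dfs$features$k, truth)) else NA,
    hack = hack[c("decision_set", "median_random_cpp")],
    n_significant_edges = if (nrow(gs) > 0)
      significance_summary(gs)$n_significant else NA,
    elapsed_sec = proc.time()[["elapsed"]] - t0
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done in %.1fs; artifacts in %s", summary$elapsed_sec, out_dir)
  invisible(summary)
}

#' Write a cohort to disk as per-subject TSV time series
#'
#' One TSV per subject (timepoints x ROIs, no header) plus a manifest CSV
#' (subject_id, path, label) and the planted-truth feature indices.
#'
#' @param cohort result of [sample_cohort()].
#' @param out_dir output directory.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$series, function(s) {
    f <- file.path(out_dir, paste0(s$subject_id, ".tsv"))
    utils::write.table(s$data, f, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    f
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(cohort$series, `[[`, "", "subject_id"),
    path = paths, label = cohort$labels)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(k = planted_truth(cohort$spec)),
                   file.path(out_dir, "planted_truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest back into time-series objects
#'
#' @param manifest_csv path to a manifest written by [write_cohort()].
#' @return list with `series` and `labels`, as [sample_cohort()] returns.
#' @export
read_cohort <- function(manifest_csv) {
  man <- utils::read.csv(manifest_csv)
  base <- dirname(manifest_csv)
  series <- lapply(seq_len(nrow(man)), function(i) {
    path <- man$path[i]
    if (!file.exists(path)) path <- file.path(base, basename(path))
    roi_ts(as.matrix(utils::read.table(path, sep = "\t")),
           subject_id = man$subject_id[i])
  })
  list(series = series, labels = as.integer(man$label))
}
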
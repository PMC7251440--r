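#' Top-K features of one local linear model
#'
#' The `K` features with the largest weights in the instance's exact local
#' linear form. `ranking = "abs"` (default) orders by `|w|`, which also
#' surfaces features that push the prediction toward the negative class;
#' `ranking = "signed"` orders by `w` itself. Ties break by ascending feature
#' index.
#'
#' @param llm a `"plnn_local"` (or plain numeric weight vector).
#' @param K how many features (>= 1); values above `d` return all `d`.
#' @param ranking `"abs"` or `"signed"`.
#' @return integer vector of feature indices (1-based), highest-ranked first.
#' @export
top_k_features <- function(llm, K, ranking = c("abs", "signed")) {
  ranking <- match.arg(ranking)
  w <- if (inherits(llm, "plnn_local")) llm$w_hat else as.numeric(llm)
  stopifnot(K >= 1)
  key <- if (ranking == "abs") -abs(w) else -w
  order(key, seq_along(w))[seq_len(min(K, length(w)))]
}

#' Mine the group-level decision feature set
#'
#' For every interpreted instance, take its top-K feature set; count for each
#' feature `f` the number of instances `n_f` whose top-K set contains it; keep
#' the features whose occurrence fraction `n_f / n_instances` is at least
#' `epsilon`. These are the features the model leans on consistently across
#' the cohort, not just for one subject.
#'
#' @param llms list of `"plnn_local"` objects (or numeric weight vectors).
#' @param K top-K size per instance.
#' @param epsilon occurrence-fraction threshold in (0, 1]; a feature is kept
#'   when its fraction is `>= epsilon`.
#' @param ranking passed to [top_k_features()].
#' @return An object of class `"decision_features"`: list with `K`, `epsilon`,
#'   `ranking`, `n_instances`, and a data.frame `features` (columns `k`,
#'   `n_f`, `fraction`, sorted by `k`).
#' @export
decision_feature_set <- function(llms, K, epsilon, ranking = c("abs", "signed")) {
  ranking <- match.arg(ranking)
  if (length(llms) == 0L) stop("empty instance list")
  stopifnot(epsilon > 0, epsilon <= 1)
  tops <- lapply(llms, top_k_features, K = K, ranking = ranking)
  counts <- table(unlist(tops))
  n <- length(llms)
  k_idx <- as.integer(names(counts))
  frac <- as.numeric(counts) / n
  keep <- frac >= epsilon
  feats <- data.frame(k = k_idx[keep], n_f = as.integer(counts)[keep],
                      fraction = frac[keep])
  feats <- feats[order(feats$k), , drop = FALSE]
  rownames(feats) <- NULL
  structure(list(K = as.integer(K), epsilon = epsilon, ranking = ranking,
                 n_instances = n, features = feats),
            class = "decision_features")
}

#' @export
print.decision_features <- function(x, ...) {
  cat(sprintf("decision feature set: K=%d, epsilon=%.2f, ranking=%s, %d/%d instances -> %d features\n",
              x$K, x$epsilon, x$ranking, x$n_instances, x$n_instances,
              nrow(x$features)))
  if (nrow(x$features)) print(utils::head(x$features, 20L))
  invisible(x)
}

#' Sweep the decision-feature count over a (K, epsilon) grid
#'
#' Evaluates [decision_feature_set()] on the full cross-product of the two
#' grids and reports the set size for each cell. Because top-K sets are
#' nested in `K` and the occurrence filter only tightens as `epsilon` grows,
#' `|F|` is nondecreasing in `K` and nonincreasing in `epsilon`.
#'
#' @inheritParams decision_feature_set
#' @param K_grid integer vector of K values.
#' @param epsilon_grid numeric vector of thresholds.
#' @return data.frame with columns `K`, `epsilon`, `n_features`.
#' @export
decision_feature_sweep <- function(llms, K_grid = seq(5L, 300L, by = 5L),
                                   epsilon_grid = seq(0.70, 0.95, by = 0.05),
                                   ranking = c("abs", "signed")) {
  ranking <- match.arg(ranking)
  stopifnot(length(K_grid) > 0, length(epsilon_grid) > 0)
  n <- length(llms)
  d <- length(if (inherits(llms[[1]], "plnn_local")) llms[[1]]$w_hat else llms[[1]])
  # count occurrences once per K, then threshold: cheaper than the naive loop
  out <- expand.grid(K = as.integer(K_grid), epsilon = epsilon_grid,
                     KEEP.OUT.ATTRS = FALSE)
  out$n_features <- NA_integer_
  for (K in unique(out$K)) {
    tops <- lapply(llms, top_k_features, K = K, ranking = ranking)
    counts <- tabulate(unlist(tops), nbins = d)
    for (e in epsilon_grid)
      out$n_features[out$K == K & out$epsilon == e] <- sum(counts / n >= e)
  }
  out
}

#' Pool held-out interpretations across cross-validation folds
#'
#' Interprets every subject exactly once, by the model of the fold where that
#' subject was held out — the per-instance population the decision-feature
#' mining operates on when run in cross-validation mode.
#'
#' @param cv a `"plnn_cv"` fitted with `keep_models = TRUE`.
#' @param x the feature matrix (or `"fc_dataset"`) the CV was run on.
#' @return list of `"plnn_local"` objects aligned with the input rows.
#' @export
pooled_cv_interpretations <- function(cv, x) {
  stopifnot(inherits(cv, "plnn_cv"))
  if (is.null(cv$models))
    stop("plnn_cv must be run with keep_models = TRUE")
  if (inherits(x, "fc_dataset")) x <- x$X
  X <- as.matrix(x)
  lapply(seq_len(nrow(X)), function(i)
    local_linear(cv$models[[cv$folds[i]]], X[i, ]))
}
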
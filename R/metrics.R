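#' Confusion-matrix metrics and AUC for binary predictions
#'
#' Thresholds predicted probabilities at `threshold` (predicted positive when
#' `p >= threshold`) and reports the confusion counts together with
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`, and `F1 = 2 TP / (2 TP + FP + FN)`. AUC is computed by the
#' Mann-Whitney rank statistic with ties averaged, equivalent to integrating
#' the ROC curve over all thresholds. With one-class labels the AUC is
#' undefined and reported as `NA`; the other metrics are still computed
#' (undefined ratios are `NaN`).
#'
#' @param probs predicted positive-class probabilities (or any monotone
#'   score for the AUC).
#' @param labels binary labels, positive class = 1.
#' @param threshold classification threshold, default 0.5.
#' @return A list of class `"plnn_metrics"` with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `f1`, `auc`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% c(0L, 1L)))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    f1 = 2 * tp / (2 * tp + fp + fn),
    auc = auc_rank(probs, labels)
  ), class = "plnn_metrics")
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of the
#' positive-class scores with ties averaged.
#'
#' @inheritParams classification_metrics
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
auc_rank <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.plnn_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.4f  specificity %.4f  accuracy %.4f  F1 %.4f  AUC %s\n",
              x$sensitivity, x$specificity, x$accuracy, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals class members across folds so every
#' fold keeps the overall class balance; the leftover samples of successive
#' classes are placed in successive folds so fold sizes differ by at most one
#' overall. Deterministic given `seed`.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, same length as `y`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.integer(y); n <- length(y)
  if (n < k) stop("need at least k samples (n = ", n, ", k = ", k, ")")
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    nc <- length(idx)
    base <- nc %/% k; extra <- nc %% k
    sizes <- rep(base, k)
    if (extra > 0L)
      sizes[((offset + seq_len(extra) - 1L) %% k) + 1L] <- base + 1L
    fold[idx] <- rep(seq_len(k), times = sizes)
    offset <- offset + extra
  }
  fold
}

#' Stratified k-fold cross-validation of the network
#'
#' Fits one model per fold on the training split and evaluates on the held-out
#' split. Fold assignment is stratified and seed-deterministic; each fold's
#' model gets its own derived seed.
#'
#' @param x feature matrix `n x d` or `"fc_dataset"`.
#' @param y binary labels (taken from `x` when it is an `"fc_dataset"`).
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and per-fold training.
#' @param keep_models keep the fitted per-fold models (needed to pool
#'   held-out interpretations across folds).
#' @param ... model settings passed to [plnn()].
#' @return A list of class `"plnn_cv"`: `folds` (assignment), per-fold
#'   `metrics`, `summary` (mean and sd of each metric across folds),
#'   held-out probabilities `heldout_prob` aligned with the input rows, and
#'   optionally `models`.
#' @export
plnn_cv <- function(x, y = NULL, k = 5L, seed = 1L, keep_models = FALSE, ...) {
  if (inherits(x, "fc_dataset")) { y <- x$y; x <- x$X }
  X <- as.matrix(x); y <- as.integer(y)
  fold <- stratified_folds(y, k = k, seed = seed)
  metrics <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  heldout <- rep(NA_real_, nrow(X))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    fit <- plnn(X[tr, , drop = FALSE], y[tr], seed = seed + 1000L * f, ...)
    pr <- predict(fit, X[te, , drop = FALSE])
    heldout[te] <- pr
    metrics[[f]] <- classification_metrics(pr, y[te])
    if (keep_models) models[[f]] <- fit
  }
  nm <- c("sensitivity", "specificity", "accuracy", "f1", "auc")
  tab <- sapply(metrics, function(m) unlist(m[nm]))
  summary <- data.frame(metric = nm, mean = rowMeans(tab),
                        sd = apply(tab, 1L, stats::sd), row.names = NULL)
  structure(list(folds = fold, metrics = metrics, summary = summary,
                 heldout_prob = heldout, models = models, k = k, seed = seed),
            class = "plnn_cv")
}

#' @export
print.plnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n", x$k, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
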
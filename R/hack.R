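#' Zero out a feature set across all instances
#'
#' Feature removal in the model's input space: the listed columns are set to
#' 0, which in Fisher-z units means "no connectivity" on those edges.
#'
#' @param X feature matrix `n x d`.
#' @param features integer feature indices (1-based).
#' @return a copy of `X` with the listed columns zeroed.
#' @export
hack_instances <- function(X, features) {
  X <- as.matrix(X)
  features <- as.integer(features)
  if (length(features) == 0L) return(X)
  if (any(features < 1L | features > ncol(X)))
    stop("feature index out of range 1..", ncol(X))
  X[, features] <- 0
  X
}

#' Perturbation ("hacking") report for a feature set
#'
#' Zeroes the given features, reruns the model, and summarizes how much the
#' predictions moved: mean CPP (change of prediction probability,
#' `mean |p - p_hacked|`), NLCI (number of label-changed instances, i.e.
#' instances whose thresholded label flips at 0.5), and the post-hack
#' sensitivity and accuracy against the original labels. The hacked forward
#' pass recomputes activation patterns from scratch — zeroing features can
#' move an instance into a different linear region, and that is part of what
#' is being measured.
#'
#' @param model a `"plnn"`.
#' @param X feature matrix `n x d` (or `"fc_dataset"`, which also supplies
#'   `labels`).
#' @param features feature indices to zero.
#' @param labels binary labels for the post-hack metrics.
#' @return list of class `"hack_report"`: `feature_set_size`, `mean_cpp`,
#'   `nlci`, `post_sensitivity`, `post_accuracy`, and per-instance `cpp`.
#' @export
hack_report <- function(model, X, features, labels = NULL) {
  if (inherits(X, "fc_dataset")) { if (is.null(labels)) labels <- X$y; X <- X$X }
  X <- as.matrix(X)
  p0 <- predict(model, X)
  p1 <- predict(model, hack_instances(X, features))
  cpp <- abs(p0 - p1)
  nlci <- sum((p0 >= 0.5) != (p1 >= 0.5))
  post <- if (!is.null(labels)) classification_metrics(p1, labels) else NULL
  structure(list(feature_set_size = length(unique(as.integer(features))),
                 mean_cpp = mean(cpp), nlci = nlci,
                 post_sensitivity = if (!is.null(post)) post$sensitivity else NA_real_,
                 post_accuracy = if (!is.null(post)) post$accuracy else NA_real_,
                 cpp = cpp),
            class = "hack_report")
}

#' @export
print.hack_report <- function(x, ...) {
  cat(sprintf("hack report: %d features zeroed | mean CPP %.4f | NLCI %d | post sens %.4f | post acc %.4f\n",
              x$feature_set_size, x$mean_cpp, x$nlci,
              x$post_sensitivity, x$post_accuracy))
  invisible(x)
}

#' Compare a feature set's CPP against random same-size sets
#'
#' A calibrated control: draws `n_draws` random feature sets of the same size
#' and reports their CPP distribution next to the candidate set's. A set the
#' model genuinely relies on should beat the bulk of random sets.
#'
#' @inheritParams hack_report
#' @param n_draws number of random sets (default 20).
#' @param seed RNG seed for the draws.
#' @return list with `mean_cpp` (candidate), `random_cpp` (vector of length
#'   `n_draws`), `median_random_cpp`.
#' @export
random_set_contrast <- function(model, X, features, n_draws = 20L, seed = 1L) {
  if (inherits(X, "fc_dataset")) X <- X$X
  X <- as.matrix(X)
  target <- hack_report(model, X, features)
  set.seed(seed)
  m <- length(unique(as.integer(features)))
  rnd <- vapply(seq_len(n_draws), function(i) {
    hack_report(model, X, sample.int(ncol(X), m))$mean_cpp
  }, numeric(1))
  list(mean_cpp = target$mean_cpp, random_cpp = rnd,
       median_random_cpp = stats::median(rnd))
}

#' Linear-SVM top-weight baseline for the hacking comparison
#'
#' Fits a linear support vector machine, ranks features by the magnitude of
#' its primal coefficient vector, zeroes the top `N`, and re-scores the SVM
#' itself on the hacked data. The SVM "probability" used for CPP is the
#' logistic squash of its (orientation-corrected) decision value, so the
#' baseline is fully deterministic.
#'
#' @param x feature matrix or `"fc_dataset"`.
#' @param y binary labels.
#' @param N number of top-|coefficient| features to zero.
#' @param cost SVM cost parameter.
#' @return list with `features` (the top-N indices), `weights` (full primal
#'   coefficient vector), `report` (a `"hack_report"` computed on the SVM's
#'   own scores), and the fitted `svm` object.
#' @export
svm_topweight_baseline <- function(x, y = NULL, N, cost = 1) {
  if (inherits(x, "fc_dataset")) { y <- x$y; x <- x$X }
  X <- as.matrix(x); y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required")
  fit <- e1071::svm(X, factor(y, levels = c(0L, 1L)), kernel = "linear",
                    scale = FALSE, cost = cost)
  w <- drop(crossprod(fit$coefs, fit$SV))
  rho <- fit$rho
  dec <- drop(X %*% w) - rho
  # e1071 orients the decision value toward the first factor level; flip so
  # positive decision values mean class 1
  if (stats::cor(dec, y) < 0) { w <- -w; rho <- -rho; dec <- -dec }
  score <- function(M) stats::plogis(drop(M %*% w) - rho)
  N <- min(max(0L, as.integer(N)), ncol(X))
  feats <- if (N > 0L) order(-abs(w), seq_along(w))[seq_len(N)] else integer(0)
  p0 <- score(X)
  p1 <- score(hack_instances(X, feats))
  post <- classification_metrics(p1, y)
  report <- structure(list(feature_set_size = length(feats),
                           mean_cpp = mean(abs(p0 - p1)),
                           nlci = sum((p0 >= 0.5) != (p1 >= 0.5)),
                           post_sensitivity = post$sensitivity,
                           post_accuracy = post$accuracy,
                           cpp = abs(p0 - p1)),
                      class = "hack_report")
  list(features = feats, weights = w, rho = rho, report = report, svm = fit)
}
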
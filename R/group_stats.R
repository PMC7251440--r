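#' Per-edge group statistics for a feature set
#'
#' For each selected edge feature, the group means (positive vs negative
#' class), their difference, and an independent two-sample t test. Welch's
#' unequal-variance test is the default; `var_equal = TRUE` gives the pooled
#' test. With `scale = "r"` the Fisher-z features are back-transformed with
#' `tanh` before averaging and testing, so means are on the correlation
#' scale.
#'
#' @param x feature matrix `n x d` or `"fc_dataset"`.
#' @param y binary labels (taken from `x` when it is an `"fc_dataset"`).
#' @param features integer feature indices.
#' @param scale `"z"` (Fisher-z units, default) or `"r"` (correlation units).
#' @param var_equal pooled-variance t test instead of Welch.
#' @param map optional [edge_index_map()] to attach ROI pair identities.
#' @return data.frame of class `"group_stats"`: columns `k`, optionally
#'   `roi_i`/`roi_j`, `mean_pos`, `mean_neg`, `mean_diff`, `t_stat`,
#'   `p_value`.
#' @export
group_stats <- function(x, y = NULL, features, scale = c("z", "r"),
                        var_equal = FALSE, map = NULL) {
  scale <- match.arg(scale)
  if (inherits(x, "fc_dataset")) { y <- x$y; x <- x$X }
  X <- as.matrix(x); y <- as.integer(y)
  features <- as.integer(features)
  stopifnot(all(features >= 1L), all(features <= ncol(X)))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each group needs at least 2 subjects for a t test")
  rows <- lapply(features, function(k) {
    a <- X[y == 1L, k]; b <- X[y == 0L, k]
    if (scale == "r") { a <- tanh(a); b <- tanh(b) }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(k = k, mean_pos = mean(a), mean_neg = mean(b),
               mean_diff = mean(a) - mean(b),
               t_stat = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  if (!is.null(map)) {
    out$roi_i <- map$roi_i[out$k]
    out$roi_j <- map$roi_j[out$k]
    out <- out[, c("k", "roi_i", "roi_j", "mean_pos", "mean_neg",
                   "mean_diff", "t_stat", "p_value")]
  }
  rownames(out) <- NULL
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Count significant edges in a group-stats table
#'
#' Partitions the rows at `alpha`. No multiplicity correction is applied by
#' default (per-edge screening convention); `adjust = "BH"` applies
#' Benjamini-Hochberg first, which is the recommended choice when the feature
#' set is large.
#'
#' @param rows a [group_stats()] table.
#' @param alpha significance level.
#' @param adjust `"none"` or `"BH"`.
#' @return list with `n_significant`, `n_not_significant`, `alpha`, `adjust`,
#'   and the (possibly adjusted) `p_values`.
#' @export
significance_summary <- function(rows, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(nrow(rows) > 0)
  p <- rows$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  list(n_significant = sum(p < alpha),
       n_not_significant = sum(p >= alpha),
       alpha = alpha, adjust = adjust, p_values = p)
}
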
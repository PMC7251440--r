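#' plnnfc: interpretable piecewise-linear networks for functional connectivity
#'
#' Fits a small fully connected network of fc-BatchNorm-LeakyReLU blocks to
#' resting-state functional-connectivity edge features and interprets it
#' exactly: within one activation region the network's logit is a linear
#' function of the input, and [local_linear()] recovers its weights and
#' intercept in closed form. See the package vignette for the model and the
#' surrounding pipeline (feature extraction, cross-validation, decision-feature
#' mining, perturbation evaluation, group statistics, synthetic cohorts).
#'
#' @keywords internal
"_PACKAGE"

#' Construct an ROI time-series object
#'
#' Wraps a numeric matrix of BOLD (or other) signals, `T` timepoints by `p`
#' ROIs, with basic validation: at least 3 timepoints, at least 2 ROIs, all
#' values finite, and every ROI column with nonzero variance.
#'
#' @param data numeric matrix, timepoints in rows, ROIs in columns.
#' @param subject_id character scalar identifying the subject.
#' @param roi_labels optional character vector of ROI names (length `p`).
#' @return An object of class `"roi_ts"`: a list with `subject_id`, `data`,
#'   `roi_labels`.
#' @export
roi_ts <- function(data, subject_id = "subject", roi_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 3L)
    stop("time series must have at least 3 timepoints, got ", nrow(data))
  if (ncol(data) < 2L)
    stop("time series must cover at least 2 ROIs, got ", ncol(data))
  if (!all(is.finite(data)))
    stop("time series contains non-finite values")
  v <- apply(data, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(roi_labels)) roi_labels[bad] else as.character(bad)
    stop("zero-variance ROI column(s): ", paste(nm, collapse = ", "))
  }
  if (!is.null(roi_labels) && length(roi_labels) != ncol(data))
    stop("roi_labels length must equal the number of ROI columns")
  structure(list(subject_id = as.character(subject_id), data = data,
                 roi_labels = roi_labels),
            class = "roi_ts")
}

#' Pearson connectivity matrix of an ROI time series
#'
#' Column-wise Pearson correlations of the ROI signals. The result is
#' symmetric with unit diagonal and entries in \[-1, 1\]; the sample vs
#' population variance convention cancels in the correlation ratio, so either
#' gives the same matrix.
#'
#' @param ts a [roi_ts()] object (or a plain matrix, coerced via `roi_ts`).
#' @return An object of class `"conn_matrix"`: list with `subject_id`, the
#'   `p x p` correlation matrix `r`, and `p`.
#' @export
pearson_matrix <- function(ts) {
  if (!inherits(ts, "roi_ts")) ts <- roi_ts(ts)
  r <- stats::cor(ts$data)
  # cor() can drift past 1 by rounding; pin the contract exactly
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  if (!is.null(ts$roi_labels)) dimnames(r) <- list(ts$roi_labels, ts$roi_labels)
  structure(list(subject_id = ts$subject_id, r = r, p = ncol(r)),
            class = "conn_matrix")
}

#' Fisher z-transform a connectivity matrix
#'
#' Applies `atanh` to the off-diagonal correlations after clipping them to
#' `[-clip, clip]`, so perfectly (anti)correlated edges stay finite. The
#' diagonal is left untouched; it never enters the feature vector.
#'
#' @param c a `"conn_matrix"`.
#' @param clip clipping bound in (0, 1); default `1 - 1e-7`.
#' @return A `"conn_matrix"` whose off-diagonal entries are Fisher z values.
#' @export
fisher_z <- function(c, clip = 1 - 1e-7) {
  stopifnot(inherits(c, "conn_matrix"), clip > 0, clip < 1)
  z <- pmin(pmax(c$r, -clip), clip)
  z <- atanh(z)
  diag(z) <- diag(c$r)
  out <- c
  out$r <- z
  out
}

#' Edge index map for p ROIs
#'
#' The canonical bijection between flat feature index `k` and ordered ROI pair
#' `(i, j)`, `i < j`. Order is row-major over the upper triangle:
#' (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p). Indices are 1-based, the R
#' convention; the order itself is fixed so feature indices are reproducible
#' across runs and exports.
#'
#' @param p number of ROIs (>= 2).
#' @param roi_labels optional ROI names.
#' @return data.frame with columns `k`, `roi_i`, `roi_j` (and `label_i`,
#'   `label_j` when labels are given); `p(p-1)/2` rows.
#' @export
edge_index_map <- function(p, roi_labels = NULL) {
  stopifnot(p >= 2)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p), use.names = FALSE)
  out <- data.frame(k = seq_along(i), roi_i = i, roi_j = j)
  if (!is.null(roi_labels)) {
    stopifnot(length(roi_labels) == p)
    out$label_i <- roi_labels[i]
    out$label_j <- roi_labels[j]
  }
  out
}

#' Flatten the upper triangle of a connectivity matrix
#'
#' Extracts the strict upper triangle in [edge_index_map()] order, giving the
#' length `p(p-1)/2` feature vector.
#'
#' @param c a `"conn_matrix"` (symmetric).
#' @return numeric vector of length `p(p-1)/2`.
#' @export
flatten_upper <- function(c) {
  stopifnot(inherits(c, "conn_matrix"))
  m <- c$r
  if (max(abs(m - t(m))) > 1e-8)
    stop("connectivity matrix is not symmetric")
  tm <- t(m)
  tm[lower.tri(tm)]  # column-major lower tri of t(m) == row-major upper tri of m
}

#' Rebuild a symmetric matrix from a flat edge vector
#'
#' Inverse of [flatten_upper()] for the off-diagonal part; the diagonal is
#' filled with `diag_value`.
#'
#' @param z numeric vector of length `p(p-1)/2`.
#' @param p number of ROIs.
#' @param diag_value value for the diagonal (default 0).
#' @return `p x p` symmetric matrix.
#' @export
unflatten_upper <- function(z, p, diag_value = 0) {
  d <- p * (p - 1L) / 2L
  stopifnot(length(z) == d)
  m <- matrix(0, p, p)
  tm <- t(m)
  tm[lower.tri(tm)] <- z
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Assemble a labelled feature dataset from ROI time series
#'
#' Runs each subject through Pearson correlation, Fisher z, and upper-triangle
#' flattening, and stacks the results into an `n x d` feature matrix with
#' binary group labels (positive class = 1).
#'
#' @param series list of [roi_ts()] objects (or matrices).
#' @param labels binary vector (0/1), one per subject.
#' @param clip clipping bound passed to [fisher_z()].
#' @return An object of class `"fc_dataset"`: list with `X` (n x d), `y`,
#'   `subject_ids`, `p`.
#' @export
build_dataset <- function(series, labels, clip = 1 - 1e-7) {
  if (length(series) == 0L) stop("empty subject list")
  if (length(series) != length(labels))
    stop("series and labels must have equal length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  series <- lapply(seq_along(series), function(s) {
    x <- series[[s]]
    if (inherits(x, "roi_ts")) x else roi_ts(x, subject_id = paste0("subject_", s))
  })
  ps <- vapply(series, function(s) ncol(s$data), integer(1))
  if (length(unique(ps)) != 1L) {
    off <- vapply(series[ps != ps[1]], `[[`, "", "subject_id")
    stop("inconsistent ROI count across subjects: ", paste(off, collapse = ", "))
  }
  p <- ps[1]
  X <- t(vapply(series, function(s) {
    flatten_upper(fisher_z(pearson_matrix(s), clip = clip))
  }, numeric(p * (p - 1L) / 2L)))
  ids <- vapply(series, `[[`, "", "subject_id")
  rownames(X) <- ids
  structure(list(X = X, y = labels, subject_ids = ids, p = p),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("fc_dataset: %d subjects, %d ROIs, %d edge features (%d positive / %d negative)\n",
              nrow(x$X), x$p, ncol(x$X), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}
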
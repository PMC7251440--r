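#' Specification of a synthetic two-group connectivity cohort
#'
#' Defines a cohort whose two groups share a latent-factor correlation
#' structure but differ on a small planted set of ROI-pair edges: the
#' positive group's target correlation is shifted by `delta` on those edges
#' (then repaired to the nearest positive-definite correlation matrix). This
#' is the ground-truth generator used to validate the whole pipeline — the
#' planted edges are what feature attribution should recover.
#'
#' @param p number of ROIs.
#' @param n_per_group subjects per group.
#' @param t_len timepoints per subject.
#' @param planted_edges two-column matrix (or list of pairs) of ROI pairs
#'   `(i, j)`, `i < j`, 1-based; `NULL` draws `n_planted` distinct pairs
#'   deterministically from `seed`.
#' @param n_planted number of planted edges when `planted_edges` is `NULL`.
#' @param delta correlation shift added on planted edges in the positive
#'   group.
#' @param base_density strength of the shared latent-factor structure
#'   (relative to unit idiosyncratic noise).
#' @param noise_sd idiosyncratic (per-ROI) noise scale.
#' @param jitter_sd per-subject correlation jitter (symmetric Gaussian
#'   perturbation, PD-repaired).
#' @param ar1 optional AR(1) coefficient for temporal autocorrelation;
#'   0 (default) gives temporally independent rows.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(p = 20L, n_per_group = 200L, t_len = 150L,
                        planted_edges = NULL, n_planted = 5L, delta = 0.3,
                        base_density = 0.5, noise_sd = 1, jitter_sd = 0.02,
                        ar1 = 0, seed = 1L) {
  p <- as.integer(p)
  stopifnot(p >= 2, n_per_group >= 1, t_len >= 3, abs(delta) < 2,
            base_density >= 0, noise_sd > 0, jitter_sd >= 0,
            ar1 >= 0, ar1 < 1)
  if (is.null(planted_edges)) {
    set.seed(seed)
    all_pairs <- edge_index_map(p)
    pick <- sample.int(nrow(all_pairs), n_planted)
    planted_edges <- as.matrix(all_pairs[pick, c("roi_i", "roi_j")])
  } else {
    if (is.list(planted_edges) && !is.matrix(planted_edges))
      planted_edges <- do.call(rbind, planted_edges)
    planted_edges <- matrix(as.integer(planted_edges), ncol = 2L,
                            dimnames = list(NULL, c("roi_i", "roi_j")))
  }
  if (nrow(planted_edges) > 0 &&
      (any(planted_edges[, 1] >= planted_edges[, 2]) ||
       any(planted_edges < 1L) || any(planted_edges > p)))
    stop("planted edges must satisfy 1 <= i < j <= p")
  structure(list(p = p, n_per_group = as.integer(n_per_group),
                 t_len = as.integer(t_len), planted_edges = planted_edges,
                 delta = delta, base_density = base_density,
                 noise_sd = noise_sd, jitter_sd = jitter_sd, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# nearest-PD repair: clip eigenvalues at `floor`, rebuild, renormalize to a
# correlation matrix
pd_repair <- function(M, floor = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- stats::cov2cor(R)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Group-level target correlation matrix
#'
#' The negative ("control") group's target is a shared latent-factor
#' correlation matrix; the positive group's target adds `delta` on the
#' planted edges and is then projected back to a positive-definite
#' correlation matrix by eigenvalue clipping. The projection must not move
#' non-planted entries by more than `delta / 10`, otherwise the configuration
#' is rejected with advice to reduce `delta`.
#'
#' @param spec a [cohort_spec()].
#' @param group `"pos"` (planted shift) or `"neg"` (baseline). The aliases
#'   `"asd"`/`"hc"` are accepted.
#' @return a `"conn_matrix"` holding the target correlation matrix.
#' @export
build_group_correlation <- function(spec, group = c("neg", "pos", "hc", "asd")) {
  group <- match.arg(group)
  group <- switch(group, asd = "pos", hc = "neg", group)
  set.seed(spec$seed)
  q <- 3L
  B <- matrix(stats::rnorm(spec$p * q, sd = sqrt(spec$base_density / q)),
              spec$p, q)
  S <- tcrossprod(B) + diag(spec$noise_sd^2, spec$p)
  R <- stats::cov2cor(S)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (group == "pos" && spec$delta != 0 && nrow(spec$planted_edges) > 0) {
    R0 <- R
    for (r in seq_len(nrow(spec$planted_edges))) {
      i <- spec$planted_edges[r, 1]; j <- spec$planted_edges[r, 2]
      v <- R[i, j] + spec$delta
      if (abs(v) >= 1)
        stop("planted shift pushes |r| past 1 on edge (", i, ",", j,
             "); use a smaller delta")
      R[i, j] <- v; R[j, i] <- v
    }
    R <- pd_repair(R)
    off <- abs(R - R0)
    pm <- matrix(FALSE, spec$p, spec$p)
    pm[spec$planted_edges] <- TRUE
    pm <- pm | t(pm)
    diag(pm) <- TRUE
    if (any(!pm) && max(off[!pm]) >= abs(spec$delta) / 10)
      stop("PD projection perturbed non-planted edges by ",
           signif(max(off[!pm]), 3),
           " (>= delta/10); use a smaller delta or weaker base structure")
  }
  structure(list(subject_id = paste0("target_", group), r = R, p = spec$p),
            class = "conn_matrix")
}

#' Sample a synthetic cohort of ROI time series
#'
#' Each subject's series is drawn as `t_len` p-variate Gaussian observations
#' with the subject's own correlation matrix: the group target plus a small
#' symmetric random jitter, PD-repaired. With `ar1 > 0` consecutive rows are
#' AR(1)-correlated while keeping the stationary cross-ROI correlation equal
#' to the target. Fully deterministic given the seed in `spec`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `series` (list of [roi_ts()], negatives first), `labels`
#'   (0/1), and `spec`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  targets <- list(neg = build_group_correlation(spec, "neg")$r,
                  pos = build_group_correlation(spec, "pos")$r)
  set.seed(spec$seed + 1L)
  series <- vector("list", 2L * spec$n_per_group)
  labels <- integer(2L * spec$n_per_group)
  s <- 0L
  for (g in c("neg", "pos")) {
    for (i in seq_len(spec$n_per_group)) {
      s <- s + 1L
      Rs <- targets[[g]]
      if (spec$jitter_sd > 0) {
        E <- matrix(stats::rnorm(spec$p^2, sd = spec$jitter_sd), spec$p)
        E <- (E + t(E)) / 2
        diag(E) <- 0
        Rs <- pd_repair(Rs + E)
      }
      L <- chol(Rs)
      W <- matrix(stats::rnorm(spec$t_len * spec$p), spec$t_len) %*% L
      if (spec$ar1 > 0) {
        X <- W
        for (t in 2:spec$t_len)
          X[t, ] <- spec$ar1 * X[t - 1L, ] + sqrt(1 - spec$ar1^2) * W[t, ]
        W <- X
      }
      lab <- if (g == "pos") 1L else 0L
      labels[s] <- lab
      series[[s]] <- roi_ts(W, subject_id = sprintf("%s_%03d", g, i))
    }
  }
  list(series = series, labels = labels, spec = spec)
}

#' Flat feature indices of the planted edges
#'
#' Maps each planted ROI pair to its position in the flattened upper-triangle
#' feature vector (see [edge_index_map()]).
#'
#' @param spec a [cohort_spec()].
#' @return sorted integer vector of feature indices (1-based).
#' @export
planted_truth <- function(spec) {
  if (nrow(spec$planted_edges) == 0L) return(integer(0))
  p <- spec$p
  i <- spec$planted_edges[, 1]; j <- spec$planted_edges[, 2]
  k <- (i - 1L) * p - i * (i - 1L) / 2L + (j - i)
  sort(as.integer(k))
}
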
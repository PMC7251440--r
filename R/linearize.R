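#' Batch normalization as a per-neuron affine map
#'
#' At prediction time batch normalization is a fixed affine function of each
#' pre-activation `u`: slope `gamma / sqrt(Var[u] + eps)` and intercept
#' `beta - gamma E[u] / sqrt(Var[u] + eps)`, using the frozen running
#' statistics.
#'
#' @param model a `"plnn"` with batch normalization.
#' @return list with one element per hidden block, each holding numeric
#'   vectors `slope` and `intercept` (one entry per neuron).
#' @export
bn_linear_form <- function(model) {
  stopifnot(inherits(model, "plnn"))
  if (!model$config$batchnorm || is.null(model$bn))
    stop("model has no batch normalization layers")
  eps <- model$config$bn_epsilon
  lapply(model$bn, function(bn) {
    if (any(bn$var < 0)) stop("negative running variance in BN statistics")
    inv <- 1 / sqrt(bn$var + eps)
    list(slope = bn$gamma * inv, intercept = bn$beta - bn$gamma * bn$mean * inv)
  })
}

#' Activation pattern of an instance
#'
#' For each hidden neuron, whether its (BN-transformed) pre-activation is
#' `>= 0` (slope-1 branch of LeakyReLU) or `< 0` (slope-`alpha` branch).
#' A pre-activation of exactly 0 takes the slope-1 branch. The pattern
#' identifies the linear region of the network that contains the instance.
#'
#' @param model a `"plnn"`.
#' @param x one instance (length-`d` vector or 1-row matrix).
#' @return list of logical vectors, one per hidden layer (`TRUE` = slope 1).
#' @export
activation_pattern <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(nrow(x) == 1L)
  fwd <- plnn_forward(model, x, keep_preact = TRUE)
  lapply(fwd$preact, function(u) drop(u) >= 0)
}

#' Exact local linear form of the network at an instance
#'
#' Within the activation region of `x`, the network's logit is exactly
#' linear: `logit(x) = w_hat . x + b_hat`. The weights are obtained by
#' folding each hidden block's BN affine map and LeakyReLU branch slopes into
#' its weight matrix and composing the layers:
#' `w_hat = W_out diag(r_H * s_H) W_H ... diag(r_1 * s_1) W_1`, where `s_l`
#' is the BN slope and `r_l` the per-neuron branch slope (1 or `alpha`);
#' intercepts accumulate through the same recursion (LeakyReLU contributes no
#' intercept of its own — both branches pass through the origin — but BN
#' does). All arithmetic is double precision, so
#' `sigmoid(w_hat . x + b_hat)` reproduces `predict(model, x)` to near
#' machine precision.
#'
#' If the model was fitted with `standardize = TRUE`, the scaler is folded
#' into `w_hat`/`b_hat` so the reported weights act on original feature
#' units.
#'
#' @param model a `"plnn"`.
#' @param x one instance on the original feature scale.
#' @param subject_id optional identifier carried into the result.
#' @return An object of class `"plnn_local"`: list with `w_hat` (length `d`),
#'   `b_hat`, `pattern` (the [activation_pattern()]), `logit`, `prob`,
#'   `subject_id`.
#' @export
local_linear <- function(model, x, subject_id = NULL) {
  stopifnot(inherits(model, "plnn"))
  xv <- as.numeric(x)
  if (length(xv) != model$config$input_dim)
    stop("feature dimension mismatch: model expects ", model$config$input_dim,
         ", got ", length(xv))
  cfg <- model$config
  H <- length(cfg$hidden)
  bnf <- if (cfg$batchnorm) bn_linear_form(model) else NULL
  pattern <- activation_pattern(model, xv)

  # accumulate x -> Wacc x + bacc through the hidden blocks
  xs <- if (!is.null(model$center)) (xv - model$center) / model$scale else xv
  Wacc <- diag(length(xs))
  bacc <- numeric(length(xs))
  for (h in seq_len(H)) {
    W <- model$W[[h]]; b <- model$b[[h]]
    s <- if (cfg$batchnorm) bnf[[h]]$slope else rep(1, nrow(W))
    t0 <- if (cfg$batchnorm) bnf[[h]]$intercept else rep(0, nrow(W))
    r <- ifelse(pattern[[h]], 1, cfg$leaky_slope)
    # block: a = r * (s * (W z + b) + t0)
    Wacc <- (r * s * W) %*% Wacc
    bacc <- r * (s * (drop(W %*% bacc) + b) + t0)
  }
  w_hat <- drop(model$W[[H + 1L]] %*% Wacc)
  b_hat <- drop(model$W[[H + 1L]] %*% bacc) + model$b[[H + 1L]]
  if (!is.null(model$center)) {
    # logit = w . (x - center)/scale + b  ==>  fold scaler into (w, b)
    w_orig <- w_hat / model$scale
    b_hat <- b_hat - sum(w_hat * model$center / model$scale)
    w_hat <- w_orig
  }
  logit <- sum(w_hat * xv) + b_hat
  structure(list(w_hat = w_hat, b_hat = b_hat, pattern = pattern,
                 logit = logit, prob = stats::plogis(logit),
                 subject_id = subject_id),
            class = "plnn_local")
}

#' @export
print.plnn_local <- function(x, ...) {
  cat(sprintf("local linear model%s: %d features, intercept %.4g, logit %.4g (p = %.4f)\n",
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              length(x$w_hat), x$b_hat, x$logit, x$prob))
  invisible(x)
}

#' Local linear forms for every row of a feature matrix
#'
#' @param model a `"plnn"`.
#' @param X matrix `n x d` or `"fc_dataset"`.
#' @return list of `"plnn_local"` objects, one per row.
#' @export
local_linear_all <- function(model, X) {
  ids <- NULL
  if (inherits(X, "fc_dataset")) { ids <- X$subject_ids; X <- X$X }
  X <- as.matrix(X)
  lapply(seq_len(nrow(X)), function(i)
    local_linear(model, X[i, ], subject_id = if (!is.null(ids)) ids[i]))
}

#' Maximum logit residual of the linearization over a dataset
#'
#' Recomputes every instance's logit twice — by the eval-mode forward pass
#' and by its folded linear form — and returns the largest absolute
#' difference. This is the operational check that the folding is exact.
#'
#' @param model a `"plnn"`.
#' @param X matrix `n x d` or `"fc_dataset"`.
#' @return maximum absolute logit residual (a single number).
#' @export
verify_faithfulness <- function(model, X) {
  if (inherits(X, "fc_dataset")) X <- X$X
  X <- as.matrix(X)
  fwd <- plnn_forward(model, X)$logit
  lin <- vapply(seq_len(nrow(X)), function(i) local_linear(model, X[i, ])$logit,
                numeric(1))
  max(abs(fwd - lin))
}

#' Export an instance's feature weights as a ranked table
#'
#' Orders the local linear weights by decreasing magnitude (ties broken by
#' ascending feature index) and joins ROI pair identities from the edge
#' index map.
#'
#' @param llm a `"plnn_local"`.
#' @param map an [edge_index_map()] for the matching `p`.
#' @param top_n how many features to keep; values larger than `d` return all.
#' @return data.frame with columns `k`, `roi_i`, `roi_j`, `weight` (plus
#'   label columns when the map has them), sorted by `|weight|` descending.
#' @export
export_instance_weights <- function(llm, map, top_n = 20L) {
  stopifnot(inherits(llm, "plnn_local"), nrow(map) == length(llm$w_hat))
  top_n <- min(max(0L, as.integer(top_n)), length(llm$w_hat))
  ord <- order(-abs(llm$w_hat), seq_along(llm$w_hat))[seq_len(top_n)]
  out <- map[ord, , drop = FALSE]
  out$weight <- llm$w_hat[ord]
  rownames(out) <- NULL
  out
}
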
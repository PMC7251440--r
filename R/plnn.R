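#' Configuration for a piecewise-linear connectivity classifier
#'
#' Collects the architecture and optimizer settings of the fc-BN-LeakyReLU
#' network. The defaults follow the reference architecture for 116-ROI
#' connectivity vectors: hidden widths 64 and 32, a single sigmoid output
#' unit, dropout ratio 0.8 (probability of *dropping* a unit), Adam with
#' learning rate 5e-4, and binary cross-entropy loss.
#'
#' @param input_dim number of input features `d`.
#' @param hidden integer vector of hidden-layer widths.
#' @param leaky_slope LeakyReLU negative-side slope `alpha` in \[0, 1).
#'   `alpha = 0` reduces to ReLU and is accepted with a warning (the exact
#'   linearization remains valid).
#' @param dropout probability of dropping a hidden unit during training,
#'   in \[0, 1). Inactive at prediction/interpretation time.
#' @param bn_epsilon variance floor `epsilon` inside batch normalization.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param batchnorm logical; `FALSE` gives the BN-free network variant.
#' @param standardize logical; if `TRUE`, features are z-scored per column
#'   before training and the scaling is folded back into reported local
#'   linear weights so interpretation stays in original feature units.
#' @param bn_momentum update rate for BN running statistics.
#' @param seed integer RNG seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `"plnn_config"`.
#' @export
plnn_config <- function(input_dim, hidden = c(64L, 32L), leaky_slope = 0.01,
                        dropout = 0.8, bn_epsilon = 1e-5,
                        learning_rate = 5e-4, epochs = 200L, batch_size = 32L,
                        batchnorm = TRUE, standardize = FALSE,
                        bn_momentum = 0.1, seed = 1L) {
  hidden <- as.integer(hidden)
  stopifnot(input_dim >= 1, all(hidden >= 1), length(hidden) >= 0,
            dropout >= 0, dropout < 1, bn_epsilon > 0,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            leaky_slope >= 0, leaky_slope < 1)
  if (leaky_slope == 0)
    warning("leaky_slope = 0 reduces LeakyReLU to ReLU; interpretation is still exact")
  structure(list(input_dim = as.integer(input_dim), hidden = hidden,
                 leaky_slope = leaky_slope, dropout = dropout,
                 bn_epsilon = bn_epsilon, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 batchnorm = isTRUE(batchnorm), standardize = isTRUE(standardize),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "plnn_config")
}

leaky_relu <- function(u, alpha) pmax(u, 0) + alpha * pmin(u, 0)

#' Initialize an untrained network
#'
#' Deterministic He-style initialization given the config seed: weights
#' `N(0, 2 / ((1 + alpha^2) fan_in))`, zero biases; BN scale 1, shift 0,
#' running mean 0, running variance 1.
#'
#' @param config a [plnn_config()].
#' @return An untrained model of class `"plnn"`, usable with [predict.plnn()]
#'   and [local_linear()].
#' @export
plnn_init <- function(config) {
  stopifnot(inherits(config, "plnn_config"))
  set.seed(config$seed)
  widths <- c(config$input_dim, config$hidden, 1L)
  H <- length(config$hidden)
  W <- vector("list", H + 1L)
  b <- vector("list", H + 1L)
  for (l in seq_len(H + 1L)) {
    fan_in <- widths[l]
    sd <- sqrt(2 / ((1 + config$leaky_slope^2) * fan_in))
    W[[l]] <- matrix(stats::rnorm(widths[l + 1L] * fan_in, sd = sd),
                     nrow = widths[l + 1L], ncol = fan_in)
    b[[l]] <- numeric(widths[l + 1L])
  }
  bn <- if (config$batchnorm) {
    lapply(seq_len(H), function(h) list(gamma = rep(1, widths[h + 1L]),
                                        beta  = rep(0, widths[h + 1L]),
                                        mean  = rep(0, widths[h + 1L]),
                                        var   = rep(1, widths[h + 1L])))
  } else NULL
  structure(list(W = W, b = b, bn = bn, config = config, widths = widths,
                 trained = FALSE, loss = numeric(0),
                 center = NULL, scale = NULL),
            class = "plnn")
}

# Eval-mode forward over a matrix X (n x d): dropout off, BN uses running
# statistics. Returns list(logit, prob) plus per-layer pre-activations when
# keep_preact = TRUE (used by activation_pattern()).
plnn_forward <- function(model, X, keep_preact = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite values in input features")
  if (ncol(X) != model$config$input_dim)
    stop("feature dimension mismatch: model expects ", model$config$input_dim,
         ", got ", ncol(X))
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  cfg <- model$config
  H <- length(cfg$hidden)
  A <- X
  pre <- if (keep_preact) vector("list", H) else NULL
  for (h in seq_len(H)) {
    Z <- tcrossprod(A, model$W[[h]])
    Z <- sweep(Z, 2L, model$b[[h]], "+")
    if (cfg$batchnorm) {
      bn <- model$bn[[h]]
      inv <- 1 / sqrt(bn$var + cfg$bn_epsilon)
      U <- sweep(sweep(Z, 2L, bn$mean), 2L, bn$gamma * inv, "*")
      U <- sweep(U, 2L, bn$beta, "+")
    } else U <- Z
    if (keep_preact) pre[[h]] <- U
    A <- leaky_relu(U, cfg$leaky_slope)
  }
  logit <- drop(tcrossprod(A, model$W[[H + 1L]])) + model$b[[H + 1L]]
  list(logit = logit, prob = stats::plogis(logit), preact = pre)
}

#' Fit a piecewise-linear connectivity classifier
#'
#' Trains the fc-BN-LeakyReLU network by minibatch Adam on binary
#' cross-entropy. `x` may be a plain numeric matrix (subjects in rows,
#' Fisher-z edge features in columns) or an `"fc_dataset"` from
#' [build_dataset()], in which case `y` is taken from it.
#'
#' Batch normalization uses batch statistics during training and updates
#' running mean/variance with momentum `bn_momentum`; prediction and
#' interpretation always use the frozen running statistics, so eval-mode
#' output is a deterministic function of (model, x).
#'
#' @param x numeric matrix `n x d`, or an `"fc_dataset"`.
#' @param y binary labels (positive class = 1); ignored when `x` is an
#'   `"fc_dataset"`.
#' @param ... settings passed to [plnn_config()].
#' @param verbose print the loss every 25 epochs.
#' @return A fitted `"plnn"` object with components `W`, `b`, `bn`, `config`,
#'   per-epoch `loss`, training `fitted` probabilities and `y`.
#' @seealso [predict.plnn()], [local_linear()], [plnn_cv()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 8), 200, 8)
#' y <- as.integer(X[, 1] - X[, 2] + rnorm(200, sd = 0.3) > 0)
#' fit <- plnn(X, y, hidden = c(8, 4), dropout = 0, epochs = 60, seed = 2)
#' mean((predict(fit, X) > 0.5) == y)
#' @export
plnn <- function(x, y = NULL, ..., verbose = FALSE) {
  if (inherits(x, "fc_dataset")) { y <- x$y; x <- x$X }
  X <- as.matrix(x); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (!all(is.finite(X))) stop("non-finite values in training features")
  cfg <- plnn_config(input_dim = ncol(X), ...)
  model <- plnn_init(cfg)  # also seeds the RNG stream used below
  if (cfg$standardize) {
    model$center <- colMeans(X)
    model$scale <- apply(X, 2L, stats::sd)
    model$scale[model$scale == 0] <- 1
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  }

  n <- nrow(X); H <- length(cfg$hidden); alpha <- cfg$leaky_slope
  # Adam state, one slot per parameter tensor
  adam <- list(t = 0L, m = list(), v = list())
  par_get <- function() c(model$W, model$b,
                          if (cfg$batchnorm) lapply(model$bn, `[[`, "gamma"),
                          if (cfg$batchnorm) lapply(model$bn, `[[`, "beta"))
  init0 <- lapply(par_get(), function(p) p * 0)
  adam$m <- init0; adam$v <- init0

  adam_step <- function(grads) {
    adam$t <<- adam$t + 1L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr_t <- cfg$learning_rate * sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
    pars <- par_get()
    for (i in seq_along(pars)) {
      adam$m[[i]] <<- b1 * adam$m[[i]] + (1 - b1) * grads[[i]]
      adam$v[[i]] <<- b2 * adam$v[[i]] + (1 - b2) * grads[[i]]^2
      pars[[i]] <- pars[[i]] - lr_t * adam$m[[i]] / (sqrt(adam$v[[i]]) + eps)
    }
    k <- 1L
    for (l in seq_len(H + 1L)) { model$W[[l]] <<- pars[[k]]; k <- k + 1L }
    for (l in seq_len(H + 1L)) { model$b[[l]] <<- pars[[k]]; k <- k + 1L }
    if (cfg$batchnorm) {
      for (h in seq_len(H)) { model$bn[[h]]$gamma <<- pars[[k]]; k <- k + 1L }
      for (h in seq_len(H)) { model$bn[[h]]$beta  <<- pars[[k]]; k <- k + 1L }
    }
  }

  loss_hist <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      nb <- length(idx)
      A <- X[idx, , drop = FALSE]; yb <- y[idx]
      # ---- forward (train mode), caching what backprop needs ----
      cache <- vector("list", H)
      for (h in seq_len(H)) {
        Z <- sweep(tcrossprod(A, model$W[[h]]), 2L, model$b[[h]], "+")
        if (cfg$batchnorm) {
          mu <- colMeans(Z)
          Zc <- sweep(Z, 2L, mu)
          va <- colMeans(Zc^2)
          inv <- 1 / sqrt(va + cfg$bn_epsilon)
          Zhat <- sweep(Zc, 2L, inv, "*")
          U <- sweep(sweep(Zhat, 2L, model$bn[[h]]$gamma, "*"), 2L,
                     model$bn[[h]]$beta, "+")
          mom <- cfg$bn_momentum
          ub <- if (nb > 1L) nb / (nb - 1L) else 1
          model$bn[[h]]$mean <- (1 - mom) * model$bn[[h]]$mean + mom * mu
          model$bn[[h]]$var  <- (1 - mom) * model$bn[[h]]$var + mom * (va * ub)
        } else { Zhat <- NULL; inv <- NULL; U <- Z }
        Act <- leaky_relu(U, alpha)
        mask <- if (cfg$dropout > 0) {
          (matrix(stats::runif(nb * ncol(Act)), nb) >= cfg$dropout) /
            (1 - cfg$dropout)
        } else NULL
        Aout <- if (is.null(mask)) Act else Act * mask
        cache[[h]] <- list(Ain = A, U = U, Zhat = Zhat, inv = inv, mask = mask)
        A <- Aout
      }
      logit <- drop(tcrossprod(A, model$W[[H + 1L]])) + model$b[[H + 1L]]
      p <- stats::plogis(logit)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(pc) + (1 - yb) * log(1 - pc))
      # ---- backward ----
      gW <- vector("list", H + 1L); gb <- vector("list", H + 1L)
      ggamma <- vector("list", H); gbeta <- vector("list", H)
      dz <- matrix((p - yb) / nb, ncol = 1L)
      gW[[H + 1L]] <- crossprod(dz, A)
      gb[[H + 1L]] <- sum(dz)
      dA <- dz %*% model$W[[H + 1L]]
      for (h in rev(seq_len(H))) {
        cc <- cache[[h]]
        if (!is.null(cc$mask)) dA <- dA * cc$mask
        dU <- dA * ifelse(cc$U >= 0, 1, alpha)
        if (cfg$batchnorm) {
          ggamma[[h]] <- colSums(dU * cc$Zhat)
          gbeta[[h]] <- colSums(dU)
          dZhat <- sweep(dU, 2L, model$bn[[h]]$gamma, "*")
          sum1 <- colSums(dZhat)
          sum2 <- colSums(dZhat * cc$Zhat)
          dZ <- sweep(dZhat, 2L, sum1 / nb) - sweep(cc$Zhat, 2L, sum2 / nb, "*")
          dZ <- sweep(dZ, 2L, cc$inv, "*")
        } else dZ <- dU
        gW[[h]] <- crossprod(dZ, cc$Ain)
        gb[[h]] <- colSums(dZ)
        if (h > 1L) dA <- dZ %*% model$W[[h]]
      }
      grads <- c(gW, gb, if (cfg$batchnorm) ggamma, if (cfg$batchnorm) gbeta)
      adam_step(grads)
    }
    loss_hist[epoch] <- ep_loss / n
    if (!is.finite(loss_hist[epoch]))
      stop("training diverged: non-finite loss at epoch ", epoch,
           " (learning rate ", cfg$learning_rate, ")")
    if (verbose && epoch %% 25L == 0L)
      message(sprintf("epoch %d  loss %.4f", epoch, loss_hist[epoch]))
  }
  model$trained <- TRUE
  model$loss <- loss_hist
  # X is already standardized here when standardize = TRUE, and plnn_forward
  # re-applies the scaler, so hand it the original-scale matrix
  Xeval <- if (cfg$standardize)
    sweep(sweep(X, 2L, model$scale, "*"), 2L, model$center, "+") else X
  model$fitted <- plnn_forward(model, Xeval)$prob
  model$y <- y
  model
}

#' Predict from a fitted piecewise-linear network
#'
#' Eval-mode forward pass: dropout disabled, batch normalization frozen at
#' its running statistics.
#'
#' @param object a `"plnn"` model.
#' @param newdata matrix `n x d` or `"fc_dataset"`.
#' @param type `"response"` (probability of the positive class), `"logit"`,
#'   or `"class"` (0/1 at `threshold`).
#' @param threshold classification threshold for `type = "class"`.
#' @param ... unused.
#' @return numeric (or integer, for `"class"`) vector of length `n`.
#' @export
predict.plnn <- function(object, newdata, type = c("response", "logit", "class"),
                         threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fc_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  fwd <- plnn_forward(object, newdata)
  switch(type,
         response = fwd$prob,
         logit = fwd$logit,
         class = as.integer(fwd$prob >= threshold))
}

#' @export
print.plnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Piecewise-linear network: %s (LeakyReLU alpha=%g, %s)\n",
              paste(x$widths, collapse = "-"), cfg$leaky_slope,
              if (cfg$batchnorm) "BatchNorm" else "no BatchNorm"))
  if (x$trained)
    cat(sprintf("Trained %d epochs (batch %d, Adam lr %g, dropout %g); final BCE %.4f\n",
                cfg$epochs, cfg$batch_size, cfg$learning_rate, cfg$dropout,
                x$loss[length(x$loss)]))
  else cat("Untrained (initialization only)\n")
  invisible(x)
}

#' @export
summary.plnn <- function(object, ...) {
  out <- list(model = object,
              metrics = if (object$trained)
                classification_metrics(object$fitted, object$y) else NULL)
  class(out) <- "summary.plnn"
  out
}

#' @export
print.summary.plnn <- function(x, ...) {
  print(x$model)
  if (!is.null(x$metrics)) {
    cat("Training-set metrics:\n")
    print(x$metrics)
  }
  invisible(x)
}

#' @export
residuals.plnn <- function(object, ...) {
  if (!object$trained) stop("model is untrained")
  object$y - object$fitted
}

#' @export
plot.plnn <- function(x, ...) {
  if (!x$trained) stop("model is untrained")
  plot(seq_along(x$loss), x$loss, type = "l", xlab = "epoch",
       ylab = "binary cross-entropy", main = "Training loss", ...)
  invisible(x)
}

#' Local linear coefficients as the model's `coef` method
#'
#' A piecewise-linear network has no single coefficient vector; within the
#' activation region of a given instance it does. `coef(model, x = instance)`
#' returns the exact local weights (intercept first), delegating to
#' [local_linear()].
#'
#' @param object a `"plnn"` model.
#' @param x a single instance (length-`d` vector or 1-row matrix).
#' @param ... unused.
#' @export
coef.plnn <- function(object, x = NULL, ...) {
  if (is.null(x))
    stop("a piecewise-linear network has per-instance coefficients; ",
         "supply the instance: coef(model, x = instance)")
  ll <- local_linear(object, x)
  c("(Intercept)" = ll$b_hat, stats::setNames(ll$w_hat, paste0("f", seq_along(ll$w_hat))))
}

#' Serialize a model to JSON / read it back
#'
#' Plain-text checkpoint holding all weights, biases, BN statistics and the
#' config, written with full numeric precision.
#'
#' @param model a `"plnn"`.
#' @param path file path.
#' @return `read_plnn` returns the `"plnn"`; `write_plnn` returns `path`
#'   invisibly.
#' @export
write_plnn <- function(model, path) {
  obj <- unclass(model)
  obj$config <- unclass(obj$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_plnn
#' @export
read_plnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- lapply(obj$W, function(w) {
    m <- as.matrix(w); storage.mode(m) <- "double"; m
  })
  obj$b <- lapply(obj$b, as.numeric)
  if (!is.null(obj$bn) && length(obj$bn))
    obj$bn <- lapply(seq_len(nrow_or_len(obj$bn)), function(h) bn_slot(obj$bn, h))
  else obj$bn <- NULL
  obj$config <- structure(obj$config, class = "plnn_config")
  obj$widths <- as.integer(obj$widths)
  structure(obj, class = "plnn")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

bn_slot <- function(bn, h) {
  if (is.data.frame(bn))
    lapply(bn[h, ], function(col) as.numeric(col[[1]]))
  else lapply(bn[[h]], as.numeric)
}
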
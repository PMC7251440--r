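# shared fixtures: tiny random models/datasets and an independent
# layer-by-layer eval-mode forward pass used as the oracle for both the
# vectorized forward and the linearization

random_model <- function(d = 10L, hidden = c(4L, 3L), seed = 1L,
                         batchnorm = TRUE, leaky_slope = 0.01,
                         randomize_bn = TRUE) {
  m <- plnn_init(plnn_config(d, hidden = hidden, seed = seed,
                             batchnorm = batchnorm,
                             leaky_slope = leaky_slope))
  if (batchnorm && randomize_bn) {
    set.seed(seed + 500L)
    for (h in seq_along(m$bn)) {
      nh <- length(m$bn[[h]]$gamma)
      m$bn[[h]]$gamma <- rnorm(nh, 1, 0.3)
      m$bn[[h]]$beta <- rnorm(nh, 0, 0.3)
      m$bn[[h]]$mean <- rnorm(nh, 0, 0.5)
      m$bn[[h]]$var <- rexp(nh) + 0.1
    }
  }
  m
}

# independent oracle: scalar loops, no reuse of plnn_forward's code path
oracle_forward <- function(model, x) {
  cfg <- model$config
  a <- as.numeric(x)
  if (!is.null(model$center)) a <- (a - model$center) / model$scale
  H <- length(cfg$hidden)
  for (h in seq_len(H)) {
    z <- as.numeric(model$W[[h]] %*% a) + model$b[[h]]
    if (cfg$batchnorm) {
      bn <- model$bn[[h]]
      u <- numeric(length(z))
      for (j in seq_along(z))
        u[j] <- bn$gamma[j] * (z[j] - bn$mean[j]) /
          sqrt(bn$var[j] + cfg$bn_epsilon) + bn$beta[j]
    } else u <- z
    a <- ifelse(u >= 0, u, cfg$leaky_slope * u)
  }
  as.numeric(model$W[[H + 1L]] %*% a) + model$b[[H + 1L]]
}

separable_data <- function(n = 200L, d = 2L, seed = 1L, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] - X[, 2] + rnorm(n, sd = noise) > 0)
  list(X = X, y = y)
}

small_cohort_dataset <- function(seed = 1L, ...) {
  spec <- cohort_spec(p = 10L, n_per_group = 40L, t_len = 120L,
                      delta = 0.4, n_planted = 3L, seed = seed, ...)
  coh <- sample_cohort(spec)
  list(ds = build_dataset(coh$series, coh$labels), spec = spec)
}
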
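test_that("BN affine form matches the algebraic rearrangement", {
  m <- random_model(d = 6L, hidden = c(4L, 3L), seed = 2L, randomize_bn = FALSE)
  eps <- m$config$bn_epsilon
  # identity BN: gamma=1, beta=0, mean=0, var chosen so slope is exactly 1
  m$bn[[1]]$var <- rep(1 - eps, 4L)
  f <- bn_linear_form(m)
  expect_equal(f[[1]]$slope, rep(1, 4L))
  expect_equal(f[[1]]$intercept, rep(0, 4L))
  # gamma=2, beta=3, mean=1, var=4-eps -> slope 1, intercept 2
  m$bn[[2]]$gamma <- rep(2, 3L); m$bn[[2]]$beta <- rep(3, 3L)
  m$bn[[2]]$mean <- rep(1, 3L); m$bn[[2]]$var <- rep(4 - eps, 3L)
  f <- bn_linear_form(m)
  expect_equal(f[[2]]$slope, rep(1, 3L))
  expect_equal(f[[2]]$intercept, rep(2, 3L))
  # zero running variance stays finite thanks to eps
  m$bn[[1]]$var <- rep(0, 4L)
  f <- bn_linear_form(m)
  expect_true(all(is.finite(f[[1]]$slope)))
  expect_equal(f[[1]]$slope, m$bn[[1]]$gamma / sqrt(eps))
  m$bn[[1]]$var <- c(-1, 0, 0, 0)
  expect_error(bn_linear_form(m), "negative running variance")
})

test_that("activation pattern records the LeakyReLU branch per neuron", {
  m <- random_model(d = 3L, hidden = c(2L), seed = 5L, batchnorm = FALSE)
  m$W <- lapply(m$W, abs); m$b <- lapply(m$b, function(b) abs(b) + 0.1)
  pat <- activation_pattern(m, c(0.5, 1, 2))  # all-positive everything
  expect_true(all(unlist(pat)))
  # pre-activation exactly zero takes the slope-1 branch
  m2 <- random_model(d = 2L, hidden = c(1L), seed = 5L, batchnorm = FALSE)
  m2$W[[1]] <- matrix(c(1, -1), 1); m2$b[[1]] <- 0
  expect_true(activation_pattern(m2, c(1, 1))[[1]])
})

test_that("linearization reproduces the forward logit exactly (the central oracle)", {
  set.seed(77)
  X <- matrix(rnorm(100 * 10), 100, 10)
  # untrained seeded model with randomized BN statistics
  m1 <- random_model(d = 10L, hidden = c(4L, 3L), seed = 13L)
  expect_lt(verify_faithfulness(m1, X), 1e-7)
  # trained model on a synthetic cohort
  sc <- small_cohort_dataset(seed = 8L)
  fit <- plnn(sc$ds, hidden = c(8L, 4L), dropout = 0.2, epochs = 40L, seed = 6L)
  expect_lt(verify_faithfulness(fit, sc$ds), 1e-7)
  # BN-free variant: recursion skips the BN folding
  fit_nb <- plnn(sc$ds, hidden = c(8L, 4L), dropout = 0.2, epochs = 40L,
                 seed = 6L, batchnorm = FALSE)
  expect_lt(verify_faithfulness(fit_nb, sc$ds), 1e-7)
  # standardized fit: scaler folded back into original units
  fit_std <- plnn(sc$ds, hidden = c(8L, 4L), dropout = 0, epochs = 30L,
                  seed = 6L, standardize = TRUE)
  expect_lt(verify_faithfulness(fit_std, sc$ds), 1e-7)
  # and sigmoid of the linear form equals the predicted probability
  ll <- local_linear(fit, sc$ds$X[1, ])
  expect_equal(plogis(sum(ll$w_hat * sc$ds$X[1, ]) + ll$b_hat),
               unname(predict(fit, sc$ds$X[1, , drop = FALSE])),
               tolerance = 1e-12)
})

test_that("degenerate single-layer model returns its own weights", {
  cfg <- plnn_config(5L, hidden = integer(0), seed = 1L, batchnorm = FALSE)
  m <- plnn_init(cfg)
  ll <- local_linear(m, rnorm(5))
  expect_equal(ll$w_hat, drop(m$W[[1]]))
  expect_equal(ll$b_hat, m$b[[1]])
})

test_that("instances sharing an activation pattern share the linear model", {
  m <- random_model(d = 6L, hidden = c(4L, 3L), seed = 31L)
  set.seed(32)
  X <- matrix(rnorm(400 * 6), 400, 6)
  pats <- apply(X, 1, function(x)
    paste(as.integer(unlist(activation_pattern(m, x))), collapse = ""))
  dup <- which(duplicated(pats) | duplicated(pats, fromLast = TRUE))
  skip_if(length(dup) < 2, "no shared activation region in the sample")
  grp <- split(dup, pats[dup])
  grp <- grp[[which(lengths(grp) >= 2)[1]]]
  l1 <- local_linear(m, X[grp[1], ]); l2 <- local_linear(m, X[grp[2], ])
  expect_equal(l1$w_hat, l2$w_hat, tolerance = 1e-12)
  expect_equal(l1$b_hat, l2$b_hat, tolerance = 1e-12)
})

test_that("within a linear region the logit responds exactly linearly", {
  m <- random_model(d = 8L, hidden = c(5L, 3L), seed = 41L)
  set.seed(42)
  x <- rnorm(8)
  ll <- local_linear(m, x)
  for (i in 1:20) {
    delta <- rnorm(8) * 1e-7  # small enough to stay inside the region
    x2 <- x + delta
    same <- identical(lapply(activation_pattern(m, x2), as.integer),
                      lapply(ll$pattern, as.integer))
    if (!same) next
    lg1 <- predict(m, matrix(x, 1), type = "logit")
    lg2 <- predict(m, matrix(x2, 1), type = "logit")
    expect_equal(lg2 - lg1, sum(ll$w_hat * delta), tolerance = 1e-6)
  }
})

test_that("w_hat equals the logit gradient away from activation boundaries", {
  m <- random_model(d = 5L, hidden = c(4L, 3L), seed = 51L)
  set.seed(52)
  for (rep in 1:5) {
    x <- rnorm(5)
    ll <- local_linear(m, x)
    num <- vapply(1:5, function(j) {
      h <- 1e-6; e <- numeric(5); e[j] <- h
      (predict(m, matrix(x + e, 1), type = "logit") -
         predict(m, matrix(x - e, 1), type = "logit")) / (2 * h)
    }, numeric(1))
    expect_equal(num, ll$w_hat, tolerance = 1e-3)
  }
})

test_that("flipping every hidden unit scales the weights by alpha per layer", {
  # Construct a 2-hidden-layer model without BN; compare the all-positive
  # pattern to the all-negative pattern: each flipped layer multiplies the
  # composed weight by alpha, so both layers flipped gives an alpha^2 factor.
  alpha <- 0.01
  cfg <- plnn_config(3L, hidden = c(2L, 2L), seed = 3L, batchnorm = FALSE,
                     leaky_slope = alpha)
  m <- plnn_init(cfg)
  m$W <- lapply(m$W, function(w) abs(w) + 0.1)  # positive weights
  m$b <- lapply(m$b, function(b) b * 0)
  x_pos <- c(1, 1, 1)    # all pre-activations positive
  x_neg <- -x_pos        # with zero biases, all pre-activations negative
  w_pos <- local_linear(m, x_pos)$w_hat
  w_neg <- local_linear(m, x_neg)$w_hat
  expect_equal(w_neg, alpha^2 * w_pos, tolerance = 1e-12)
})

test_that("first-layer scale covariance holds on a one-hidden-layer model", {
  cfg <- plnn_config(4L, hidden = c(3L), seed = 9L, batchnorm = TRUE)
  m <- plnn_init(cfg)
  set.seed(10)
  m$bn[[1]]$mean <- rnorm(3); m$bn[[1]]$var <- rexp(3) + 0.5
  x <- rnorm(4)
  ll1 <- local_linear(m, x)
  c_scale <- 3
  m2 <- m; m2$W[[1]] <- c_scale * m$W[[1]]
  ll2 <- local_linear(m2, c(x))
  # with BN statistics held fixed and identical activation patterns, w_hat
  # scales by c through the first layer
  same_pat <- identical(lapply(ll1$pattern, as.integer),
                        lapply(local_linear(m2, x)$pattern, as.integer))
  if (same_pat) expect_equal(ll2$w_hat, c_scale * ll1$w_hat, tolerance = 1e-10)
  expect_lt(verify_faithfulness(m2, matrix(rnorm(40), 10, 4)), 1e-7)
})

test_that("exported weight tables rank by |weight| with index tie-breaks", {
  ll <- structure(list(w_hat = c(3, -5, 1, -3), b_hat = 0.2,
                       pattern = list(), logit = 0, prob = 0.5,
                       subject_id = "s1"),
                  class = "plnn_local")
  map <- edge_index_map(4)[1:4, ]
  tab <- export_instance_weights(ll, map, top_n = 10L)
  expect_equal(tab$weight, c(-5, 3, -3, 1))  # |w| desc, ties by index asc
  expect_equal(tab$k, c(2L, 1L, 4L, 3L))
  expect_identical(nrow(export_instance_weights(ll, map, top_n = 0L)), 0L)
  expect_equal(sum(export_instance_weights(ll, map, top_n = 4L)$weight),
               sum(ll$w_hat))
})
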
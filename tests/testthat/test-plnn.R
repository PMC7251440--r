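test_that("initialization is deterministic and shapes chain correctly", {
  cfg <- plnn_config(10L, hidden = c(4L, 3L), seed = 99L)
  m1 <- plnn_init(cfg); m2 <- plnn_init(cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(dim(m1$W[[1]]), c(4L, 10L))
  expect_identical(dim(m1$W[[2]]), c(3L, 4L))
  expect_identical(dim(m1$W[[3]]), c(1L, 3L))
  expect_true(all(vapply(m1$bn, function(b) all(b$gamma == 1) &&
                           all(b$beta == 0) && all(b$mean == 0) &&
                           all(b$var == 1), logical(1))))
  expect_warning(plnn_config(5L, leaky_slope = 0), "ReLU")
})

test_that("all-zero weights give probability 0.5 and eval forward matches the oracle", {
  m <- random_model(d = 8L, hidden = c(5L, 3L), seed = 3L)
  z <- lapply(m$W, function(w) w * 0)
  m0 <- m; m0$W <- z
  expect_equal(predict(m0, matrix(rnorm(8), 1)), 0.5)

  # hand-rolled layer-by-layer recomputation, including rescaled BN gamma
  set.seed(10)
  X <- matrix(rnorm(20 * 8), 20, 8)
  expect_equal(predict(m, X, type = "logit"),
               apply(X, 1, function(x) oracle_forward(m, x)),
               tolerance = 1e-12)
  m$bn[[1]]$gamma <- m$bn[[1]]$gamma * 2.5
  expect_equal(predict(m, X, type = "logit"),
               apply(X, 1, function(x) oracle_forward(m, x)),
               tolerance = 1e-12)
  expect_error(predict(m, matrix(c(NA, rnorm(7)), 1)), "non-finite")
})

test_that("training learns separable data and the loss descends", {
  sep <- separable_data(200L, seed = 5L)
  fit <- plnn(sep$X, sep$y, hidden = c(8L, 4L), dropout = 0,
              learning_rate = 5e-3, epochs = 100L, seed = 7L)
  expect_gte(mean((fit$fitted >= 0.5) == sep$y), 0.95)
  # descent sanity with no dropout and a tiny learning rate
  fit2 <- plnn(sep$X, sep$y, hidden = c(8L, 4L), dropout = 0,
               learning_rate = 1e-4, epochs = 20L, seed = 7L)
  expect_lte(fit2$loss[length(fit2$loss)], fit2$loss[1])
  expect_error(plnn(sep$X, rep(1L, 200L)), "both classes")
})

test_that("fixed seed reproduces training bitwise; label permutation is chance-level", {
  sep <- separable_data(120L, d = 6L, seed = 2L, noise = 0.5)
  f1 <- plnn(sep$X, sep$y, hidden = c(6L, 3L), epochs = 15L, seed = 11L)
  f2 <- plnn(sep$X, sep$y, hidden = c(6L, 3L), epochs = 15L, seed = 11L)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$bn, f2$bn)

  set.seed(31)
  yperm <- sample(sep$y)
  cvp <- plnn_cv(sep$X, yperm, k = 5L, seed = 8L, hidden = c(6L, 3L),
                 dropout = 0.2, epochs = 40L)
  acc <- cvp$summary$mean[cvp$summary$metric == "accuracy"]
  expect_gte(acc, 0.4); expect_lte(acc, 0.6)
})

test_that("backprop direction matches central-difference gradients", {
  # Independent oracle: recompute the full-batch train-mode BCE loss (batch
  # statistics, no dropout) by central differences at the initial parameters.
  # The first Adam step moves each parameter by ~ -lr * sign(gradient), so
  # after one single-batch epoch the update sign must oppose the numerical
  # gradient wherever the gradient is not negligible.
  d <- 4L; n <- 16L
  set.seed(22)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(1L, 0L), n / 2)

  init <- plnn_init(plnn_config(d, hidden = c(3L, 2L), seed = 21L,
                                dropout = 0, batch_size = n, epochs = 1L,
                                learning_rate = 1e-6))
  eps <- init$config$bn_epsilon; alpha <- init$config$leaky_slope
  train_loss <- function(model) {
    A <- X
    for (h in 1:2) {
      Z <- sweep(tcrossprod(A, model$W[[h]]), 2, model$b[[h]], "+")
      mu <- colMeans(Z); va <- colMeans(sweep(Z, 2, mu)^2)
      Zhat <- sweep(sweep(Z, 2, mu), 2, 1 / sqrt(va + eps), "*")
      U <- sweep(sweep(Zhat, 2, model$bn[[h]]$gamma, "*"), 2,
                 model$bn[[h]]$beta, "+")
      A <- pmax(U, 0) + alpha * pmin(U, 0)
    }
    p <- plogis(drop(tcrossprod(A, model$W[[3]])) + model$b[[3]])
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }

  fit <- plnn(X, y, hidden = c(3L, 2L), seed = 21L, dropout = 0,
              batch_size = n, epochs = 1L, learning_rate = 1e-6)
  h <- 1e-6
  check_coord <- function(set_fun, get_delta) {
    mp <- init; mm <- init
    mp <- set_fun(mp, +h); mm <- set_fun(mm, -h)
    g <- (train_loss(mp) - train_loss(mm)) / (2 * h)
    if (abs(g) > 1e-4) expect_lt(sign(get_delta(fit, init)) * sign(g), 0)
  }
  for (i in 1:3) for (j in 1:4)
    check_coord(function(m, v) { m$W[[1]][i, j] <- m$W[[1]][i, j] + v; m },
                function(f, m0) f$W[[1]][i, j] - m0$W[[1]][i, j])
  for (j in 1:2)
    check_coord(function(m, v) { m$bn[[2]]$gamma[j] <- m$bn[[2]]$gamma[j] + v; m },
                function(f, m0) f$bn[[2]]$gamma[j] - m0$bn[[2]]$gamma[j])
  for (j in 1:3)
    check_coord(function(m, v) { m$b[[1]][j] <- m$b[[1]][j] + v; m },
                function(f, m0) f$b[[1]][j] - m0$b[[1]][j])
  check_coord(function(m, v) { m$W[[3]][1, 1] <- m$W[[3]][1, 1] + v; m },
              function(f, m0) f$W[[3]][1, 1] - m0$W[[3]][1, 1])
})

test_that("confusion metrics satisfy the defining identities", {
  # TP=5, FN=5, TN=7, FP=3: probabilities placed around the 0.5 threshold
  probs <- c(rep(0.9, 5), rep(0.1, 5), rep(0.2, 7), rep(0.8, 3))
  labels <- c(rep(1, 10), rep(0, 10))
  mt <- classification_metrics(probs, labels)
  expect_identical(c(mt$tp, mt$fn, mt$tn, mt$fp), c(5L, 5L, 7L, 3L))
  expect_equal(mt$sensitivity, 0.5)
  expect_equal(mt$specificity, 0.7)
  expect_equal(mt$accuracy, 0.6)
  expect_equal(mt$f1, 10 / 18)
  # identities: sensitivity*(TP+FN) == TP; accuracy is the prevalence-weighted
  # mix of sensitivity and specificity
  expect_equal(mt$sensitivity * (mt$tp + mt$fn), mt$tp)
  prev <- mean(labels)
  expect_equal(mt$accuracy, prev * mt$sensitivity + (1 - prev) * mt$specificity)

  perfect <- classification_metrics(c(0.99, 0.99, 0.01), c(1, 1, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "f1", "auc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, f1 = 1, auc = 1))
  expect_equal(classification_metrics(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_true(is.na(classification_metrics(runif(5), rep(1, 5))$auc))
})

test_that("rank-based AUC agrees with an independent ROC integration", {
  skip_if_not_installed("pROC")
  set.seed(12)
  probs <- runif(80)
  labels <- rbinom(80, 1, plogis(3 * (probs - 0.5)))
  expect_equal(auc_rank(probs, labels),
               as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("stratified folds are deterministic, stratified, and near-equal", {
  y <- c(rep(1L, 403L), rep(0L, 468L))  # 871 subjects
  f1 <- stratified_folds(y, k = 5L, seed = 17L)
  f2 <- stratified_folds(y, k = 5L, seed = 17L)
  expect_identical(f1, f2)
  expect_identical(sort(as.integer(table(f1)), decreasing = TRUE),
                   c(175L, 174L, 174L, 174L, 174L))
  # every fold contains both classes in near-stratified proportion
  for (k in 1:5) {
    tab <- table(y[f1 == k])
    expect_true(all(tab > 0))
    expect_lt(abs(mean(y[f1 == k]) - mean(y)), 0.01)
  }
  expect_error(stratified_folds(c(0L, 1L), k = 5L), "at least k")
})

test_that("cross-validation on a separable synthetic cohort is accurate", {
  spec <- cohort_spec(p = 10L, n_per_group = 60L, t_len = 200L, delta = 0.5,
                      n_planted = 4L, seed = 2L)
  coh <- sample_cohort(spec)
  sc <- list(ds = build_dataset(coh$series, coh$labels))
  cv <- plnn_cv(sc$ds, k = 5L, seed = 2L, hidden = c(12L, 6L), dropout = 0.1,
                epochs = 100L)
  expect_gte(cv$summary$mean[cv$summary$metric == "accuracy"], 0.9)
  cv2 <- plnn_cv(sc$ds, k = 5L, seed = 2L, hidden = c(12L, 6L), dropout = 0.1,
                 epochs = 100L)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$heldout_prob, cv2$heldout_prob)
})

test_that("model JSON checkpoints round-trip through write_plnn/read_plnn", {
  sep <- separable_data(100L, d = 5L, seed = 9L)
  fit <- plnn(sep$X, sep$y, hidden = c(4L, 3L), epochs = 10L, seed = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_plnn(fit, path)
  back <- read_plnn(path)
  X <- matrix(rnorm(10 * 5), 10, 5)
  expect_equal(predict(back, X, type = "logit"),
               predict(fit, X, type = "logit"), tolerance = 1e-12)
})
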
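# Levenberg-Marquardt shallow-network training: forward pass, Jacobian,
# LM step behaviour, early stopping, and the S3 interface.

test_that("forward pass matches hand computation on fixed toy weights", {
  # 2 inputs, 1 hidden neuron: W = (0.5, -0.25), b_h = 0.1,
  # w_out = 2, b_out = -0.3; x = (0.4, 0.8)
  w <- c(0.5, -0.25, 0.1, 2, -0.3)
  x <- matrix(c(0.4, 0.8), 1, 2)
  by_hand <- 2 * tanh(0.5 * 0.4 - 0.25 * 0.8 + 0.1) - 0.3
  expect_equal(arthronirs:::forward_scaled(w, x, 2, 1), by_hand)
  # all-zero weights predict the (scaled) output bias
  expect_equal(arthronirs:::forward_scaled(rep(0, 5), x, 2, 1), 0)
})

test_that("a small-weight network is linear to third order", {
  eps <- 1e-3
  w <- c(eps * 0.7, eps * (-0.2), 0, 1, 0)  # 2-input, 1 hidden
  x <- matrix(runif(20, -1, 1), 10, 2)
  pred <- arthronirs:::forward_scaled(w, x, 2, 1)
  linear <- eps * (0.7 * x[, 1] - 0.2 * x[, 2])
  expect_lt(max(abs(pred - linear)), 10 * eps^3)
})

test_that("prediction Jacobian matches central finite differences", {
  for (k in 1:100) {
    net <- toy_net(d = sample(1:4, 1), h = sample(1:3, 1), seed = k)
    J <- ann_jacobian(net$w, net$Xs, net$h)
    Jfd <- fd_jacobian_oracle(net$w, net$Xs, net$h)
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("Jacobian structure follows the chain rule", {
  net <- toy_net()
  J <- ann_jacobian(net$w, net$Xs, net$h)
  f <- arthronirs:::forward_scaled(net$w, net$Xs, net$d, net$h,
                                   keep_hidden = TRUE)
  # output-weight columns are the hidden activations; bias column is 1
  p <- arthronirs:::n_weights(net$d, net$h)
  expect_equal(J[, (p - net$h):(p - 1)], f$Z, ignore_attr = TRUE)
  expect_equal(J[, p], rep(1, 5))
  # duplicated sample gives a duplicated row
  X2 <- net$Xs[c(1, 1, 2), ]
  J2 <- ann_jacobian(net$w, X2, net$h)
  expect_equal(J2[1, ], J2[2, ])
})

test_that("LM step accepts only SSE-reducing updates and honours limits", {
  net <- toy_net(d = 2, h = 2, seed = 3)
  Xs <- matrix(runif(40, -1, 1), 20, 2)
  ys <- arthronirs:::forward_scaled(net$w, Xs, 2, 2)
  # zero residuals: stationary point, step accepted with unchanged weights
  st <- arthronirs:::lm_step(net$w, Xs, ys, 2, mu = 1e-3)
  expect_true(st$accepted)
  expect_equal(st$w, net$w)
  # large-mu limit: step approaches the scaled gradient J'e / mu
  w0 <- net$w + 0.3
  e <- ys - arthronirs:::forward_scaled(w0, Xs, 2, 2)
  g <- crossprod(ann_jacobian(w0, Xs, 2), e)
  st <- arthronirs:::lm_step(w0, Xs, ys, 2, mu = 1e8)
  expect_equal(st$w - w0, as.vector(g) / 1e8, tolerance = 1e-3)
})

test_that("training on noiseless linear data matches the OLS oracle", {
  set.seed(4)
  x <- matrix(runif(120, -1, 1), 60, 2)
  y <- 2 * x[, 1] - 1
  fit <- ann_lm(x, y, n_hidden = 1, seed = 2,
                control = ann_control(max_epochs = 300, n_restarts = 2))
  ols <- lm(y ~ x)
  xt <- matrix(runif(40, -1, 1), 20, 2)
  pred <- predict(fit, xt)
  oracle <- cbind(1, xt) %*% coef(ols)
  expect_lt(sqrt(mean((pred - oracle)^2)), 1e-3 * sd(y))
})

test_that("accepted LM epochs never increase the training SSE", {
  set.seed(5)
  x <- matrix(runif(100), 50, 2)
  y <- sin(3 * x[, 1]) + 0.5 * x[, 2] + rnorm(50, 0, 0.05)
  fit <- ann_lm(x, y, n_hidden = 3, seed = 6,
                control = ann_control(max_epochs = 60, n_restarts = 1))
  expect_true(all(diff(fit$train_sse) <= 1e-12))
})

test_that("validation early stopping halts after six failures", {
  # validation target unrelated to training target: validation error
  # cannot keep improving, training must stop well before max_epochs
  set.seed(7)
  x <- matrix(runif(80), 40, 2)
  y <- x[, 1]
  xv <- matrix(runif(40), 20, 2)
  yv <- rnorm(20, 10, 0.1)  # far off-scale: monotone-worsening val error
  fit <- ann_lm(x, y, xv, yv, n_hidden = 2, seed = 8,
                control = ann_control(max_epochs = 500, n_restarts = 1))
  expect_true(fit$stop_reason %in% c("val_failures", "converged"))
  expect_lt(fit$epochs_run, 500)
  if (fit$stop_reason == "val_failures") {
    # the last six epochs brought no new validation minimum
    v <- fit$val_sse
    expect_gte(min(utils::tail(v, 6)), min(v))
  }
})

test_that("fits are deterministic under a seed", {
  set.seed(9)
  x <- matrix(runif(60), 30, 2)
  y <- x[, 1] - x[, 2] + rnorm(30, 0, 0.1)
  f1 <- ann_lm(x, y, n_hidden = 2, seed = 11)
  f2 <- ann_lm(x, y, n_hidden = 2, seed = 11)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$val_sse, f2$val_sse)
})

test_that("degenerate targets yield a constant predictor with a warning", {
  x <- matrix(runif(20), 10, 2)
  expect_warning(fit <- ann_lm(x, rep(7, 10), n_hidden = 2, seed = 1),
                 "zero variance")
  expect_equal(predict(fit, x), rep(7, 10))
})

test_that("the S3 surface behaves like a regression model object", {
  set.seed(10)
  x <- matrix(runif(60), 30, 2)
  y <- 3 * x[, 1] + rnorm(30, 0, 0.05)
  fit <- ann_lm(x, y, n_hidden = 2, seed = 3,
                control = ann_control(max_epochs = 50, n_restarts = 1))
  expect_output(print(fit), "Levenberg-Marquardt")
  expect_output(print(summary(fit)), "architecture")
  expect_length(coef(fit), arthronirs:::n_weights(2, 2))
  expect_named(coef(fit, unpacked = TRUE), c("W", "b_h", "w_out", "b_out"))
  expect_length(residuals(fit), 30)
  expect_error(predict(fit, matrix(1, 2, 5)), "columns")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30L, 3L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_json(fit, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("hidden-width grid search respects the architecture cap", {
  set.seed(12)
  x <- matrix(runif(60), 30, 2)
  y <- x[, 1]^2
  fit <- ann_lm_grid(x, y, hidden = c(1, 2, 12), seed = 4,
                     control = ann_control(max_epochs = 30, n_restarts = 1))
  expect_lte(fit$n_hidden, 8)
})

test_that("LM agrees with an independent Levenberg-Marquardt optimiser", {
  skip_if_not_installed("minpack.lm")
  set.seed(13)
  x <- matrix(runif(80, -1, 1), 40, 2)
  y <- tanh(1.5 * x[, 1] - 0.5 * x[, 2]) + rnorm(40, 0, 0.02)
  fit <- ann_lm(x, y, n_hidden = 2, seed = 5,
                control = ann_control(max_epochs = 300, n_restarts = 3))
  # same architecture fitted by minpack.lm from the package's solution
  # neighbourhood: both should reach (near-)identical training SSE
  Xs <- arthronirs:::minmax_apply(x, fit$scaling$x)
  ys <- as.vector(arthronirs:::minmax_apply(matrix(y, ncol = 1),
                                            fit$scaling$y))
  resid_fn <- function(w) ys - arthronirs:::forward_scaled(w, Xs, 2, 2)
  ref <- minpack.lm::nls.lm(par = fit$weights, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  sse_pkg <- sum(resid_fn(fit$weights)^2)
  sse_ref <- sum(resid_fn(ref$par)^2)
  expect_lt(abs(sse_pkg - sse_ref) / max(sse_ref, 1e-8), 0.05)
})
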
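# Levenberg-Marquardt training of single-hidden-layer regression
# networks (tanh hidden layer, linear output), written from scratch:
# this damped Gauss-Newton optimiser over the full batch, with
# validation-based early stopping and restarts, is the modelling core
# of the package.

#' Training control parameters for [ann_lm()]
#'
#' @param max_epochs Maximum full-batch Levenberg-Marquardt epochs.
#' @param mu_init,mu_up,mu_down,mu_max Damping schedule: initial mu,
#'   multiplier on rejection (> 1), multiplier on acceptance (in (0,1)),
#'   and the overflow cap (training stops with reason `"mu_overflow"`).
#' @param max_val_failures Consecutive epochs without a new validation
#'   SSE minimum before early stopping (default 6).
#' @param n_restarts Seeded random restarts; the restart with the lowest
#'   validation SSE wins.
#' @param min_sse Training SSE below which optimisation stops.
#' @return A list of class `"ann_control"`.
#' @export
ann_control <- function(max_epochs = 200L, mu_init = 1e-3, mu_up = 10,
                        mu_down = 0.1, mu_max = 1e10,
                        max_val_failures = 6L, n_restarts = 3L,
                        min_sse = 1e-12) {
  stopifnot(mu_up > 1, mu_down > 0, mu_down < 1, mu_init > 0,
            max_epochs >= 1, n_restarts >= 1)
  structure(list(max_epochs = as.integer(max_epochs), mu_init = mu_init,
                 mu_up = mu_up, mu_down = mu_down, mu_max = mu_max,
                 max_val_failures = as.integer(max_val_failures),
                 n_restarts = as.integer(n_restarts), min_sse = min_sse),
            class = "ann_control")
}

# --- weight packing -------------------------------------------------------
# w = [W (h x d, row-major by neuron), b_h (h), w_out (h), b_out (1)]

n_weights <- function(d, h) h * (d + 2L) + 1L

unpack_weights <- function(w, d, h) {
  list(W = matrix(w[seq_len(h * d)], h, d, byrow = TRUE),
       b_h = w[h * d + seq_len(h)],
       w_out = w[h * (d + 1L) + seq_len(h)],
       b_out = w[h * (d + 2L) + 1L])
}

pack_weights <- function(W, b_h, w_out, b_out) {
  c(as.vector(t(W)), b_h, w_out, b_out)
}

# Nguyen-Widrow-style initialisation (uses the current RNG stream).
init_weights <- function(d, h) {
  scale <- 0.7 * h^(1 / max(d, 1))
  W <- matrix(runif(h * d, -1, 1), h, d)
  nrm <- sqrt(rowSums(W^2)); nrm[nrm == 0] <- 1
  W <- scale * W / nrm
  b_h <- runif(h, -scale, scale)
  pack_weights(W, b_h, runif(h, -0.5, 0.5), 0)
}

# Forward pass in scaled space. Returns yhat and (optionally) the
# hidden activations needed by the Jacobian.
forward_scaled <- function(w, Xs, d, h, keep_hidden = FALSE) {
  p <- unpack_weights(w, d, h)
  Z <- tanh(sweep(Xs %*% t(p$W), 2, p$b_h, `+`))
  yhat <- as.vector(Z %*% p$w_out + p$b_out)
  if (keep_hidden) list(yhat = yhat, Z = Z, w_out = p$w_out) else yhat
}

#' Prediction Jacobian of a shallow tanh network
#'
#' Matrix of partial derivatives of the (scaled) network output with
#' respect to every weight, one row per sample, in the internal packing
#' order (input weights by neuron, hidden biases, output weights, output
#' bias). The residual Jacobian used by the Levenberg-Marquardt step is
#' its negative.
#'
#' @param w Packed weight vector.
#' @param Xs Scaled input matrix (samples x inputs).
#' @param n_hidden Hidden-layer width.
#' @return A `nrow(Xs)` x `length(w)` matrix.
#' @export
ann_jacobian <- function(w, Xs, n_hidden) {
  Xs <- as.matrix(Xs)
  d <- ncol(Xs); h <- as.integer(n_hidden)
  if (nrow(Xs) == 0) stopf("batch must be nonempty")
  if (length(w) != n_weights(d, h)) stopf("weight vector has wrong length")
  f <- forward_scaled(w, Xs, d, h, keep_hidden = TRUE)
  D <- (1 - f$Z^2) * matrix(f$w_out, nrow(Xs), h, byrow = TRUE)
  JW <- D[, rep(seq_len(h), each = d), drop = FALSE] *
    Xs[, rep(seq_len(d), times = h), drop = FALSE]
  cbind(JW, D, f$Z, 1)
}

# One Levenberg-Marquardt update from weights w: solves
# (J'J + mu I) delta = J'e with J the prediction Jacobian and e the
# residuals; retries with mu * mu_up until the training SSE decreases
# or mu exceeds mu_max. On acceptance mu is relaxed by mu_down.
lm_step <- function(w, Xs, ys, n_hidden, mu, control = ann_control()) {
  d <- ncol(Xs); h <- as.integer(n_hidden)
  e <- ys - forward_scaled(w, Xs, d, h)
  sse <- sum(e^2)
  J <- ann_jacobian(w, Xs, h)
  JtJ <- crossprod(J)
  g <- crossprod(J, e)
  p <- length(w)
  repeat {
    delta <- tryCatch(solve(JtJ + mu * diag(p), g), error = function(err) NULL)
    if (!is.null(delta)) {
      w_new <- w + as.vector(delta)
      e_new <- ys - forward_scaled(w_new, Xs, d, h)
      sse_new <- sum(e_new^2)
      if (is.finite(sse_new) && sse_new < sse) {
        return(list(w = w_new, mu = max(mu * control$mu_down, 1e-20),
                    accepted = TRUE, sse = sse_new))
      }
      if (sse <= control$min_sse) {
        return(list(w = w, mu = mu, accepted = TRUE, sse = sse))
      }
    }
    mu <- mu * control$mu_up
    if (mu > control$mu_max) {
      return(list(w = w, mu = mu, accepted = FALSE, sse = sse))
    }
  }
}

# min-max scaling to [-1, 1], parameters from the calibration set only
minmax_fit <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant columns map to a constant
  list(lo = lo, span = span)
}
minmax_apply <- function(x, sc) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, sc$lo, `-`), 2, sc$span / 2, `/`) - 1
}
minmax_invert_y <- function(ys, sc) (ys + 1) * sc$span / 2 + sc$lo

#' Fit a shallow neural network by Levenberg-Marquardt
#'
#' Trains a single-hidden-layer regression network (hyperbolic-tangent
#' hidden units, linear output) with full-batch Levenberg-Marquardt
#' damped Gauss-Newton steps. Inputs and target are min-max scaled to
#' \[-1, 1\] using the calibration data only. Training stops early once
#' the validation SSE has failed to reach a new minimum for
#' `max_val_failures` (default 6) successive epochs, and the weights at
#' the best validation epoch are kept. Several seeded random restarts
#' are run and the restart with the lowest validation SSE is returned.
#'
#' @param x Calibration inputs, matrix (samples x channels).
#' @param y Calibration targets, numeric vector.
#' @param x_val,y_val Validation set (disjoint subjects). If omitted,
#'   the calibration set doubles as validation (no early-stop benefit).
#' @param n_hidden Hidden-layer width, 1-8.
#' @param control An [ann_control()].
#' @param seed Integer seed making the fit deterministic.
#' @return An object of class `"ann_lm"` with elements `weights`
#'   (packed), `n_hidden`, `scaling`, `epochs_run`, `stop_reason`
#'   (`"val_failures"`, `"max_epochs"` or `"mu_overflow"`),
#'   `train_sse`/`val_sse` trajectories, `best_val_sse`, `fitted`
#'   (calibration predictions in original units), and the call.
#' @examples
#' x <- matrix(runif(60), 30, 2)
#' y <- 2 * x[, 1] - x[, 2] + rnorm(30, 0, 0.01)
#' fit <- ann_lm(x, y, n_hidden = 2, seed = 1,
#'               control = ann_control(max_epochs = 50, n_restarts = 1))
#' print(fit)
#' @export
ann_lm <- function(x, y, x_val = NULL, y_val = NULL, n_hidden = 2L,
                   control = ann_control(), seed = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (nrow(x) == 0) stopf("calibration set is empty")
  h <- as.integer(n_hidden)
  if (h < 1 || h > 8) stopf("n_hidden must be in 1..8")
  if (is.null(x_val)) { x_val <- x; y_val <- y }
  x_val <- as.matrix(x_val); y_val <- as.numeric(y_val)
  d <- ncol(x)

  sx <- minmax_fit(x)
  sy <- minmax_fit(matrix(y, ncol = 1))
  Xs <- minmax_apply(x, sx)
  ys <- as.vector(minmax_apply(matrix(y, ncol = 1), sy))
  Xv <- minmax_apply(x_val, sx)
  yv <- as.vector(minmax_apply(matrix(y_val, ncol = 1), sy))

  if (var(y) == 0) {
    warning("target has zero variance; returning a constant predictor")
    w <- rep(0, n_weights(d, h))
    w[length(w)] <- -1  # scaled value of the constant target
    fit <- new_ann_lm(w, h, d, sx, sy, 0L, "degenerate_target",
                      numeric(0), numeric(0), sum((yv)^2), match.call())
    fit$fitted <- predict(fit, x)
    return(fit)
  }

  best <- NULL
  for (r in seq_len(control$n_restarts)) {
    res <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, r),
                     train_one(Xs, ys, Xv, yv, h, control))
    if (is.null(best) || res$best_val_sse < best$best_val_sse) best <- res
  }
  fit <- new_ann_lm(best$w, h, d, sx, sy, best$epochs, best$stop_reason,
                    best$train_sse, best$val_sse, best$best_val_sse,
                    match.call())
  fit$fitted <- predict(fit, x)
  fit$residuals_cal <- y - fit$fitted
  fit
}

new_ann_lm <- function(w, h, d, sx, sy, epochs, stop_reason,
                       train_sse, val_sse, best_val_sse, call) {
  structure(list(weights = w, n_hidden = h, n_inputs = d,
                 scaling = list(x = sx, y = sy),
                 epochs_run = epochs, stop_reason = stop_reason,
                 train_sse = train_sse, val_sse = val_sse,
                 best_val_sse = best_val_sse, call = call),
            class = "ann_lm")
}

# single restart: LM epochs with validation early stopping
train_one <- function(Xs, ys, Xv, yv, h, control) {
  d <- ncol(Xs)
  w <- init_weights(d, h)
  mu <- control$mu_init
  best_w <- w
  best_val <- sum((yv - forward_scaled(w, Xv, d, h))^2)
  fails <- 0L
  tr_sse <- numeric(0); va_sse <- numeric(0)
  stop_reason <- "max_epochs"
  epochs <- 0L
  for (ep in seq_len(control$max_epochs)) {
    st <- lm_step(w, Xs, ys, h, mu, control)
    if (!st$accepted) { stop_reason <- "mu_overflow"; break }
    w <- st$w; mu <- st$mu
    epochs <- ep
    val <- sum((yv - forward_scaled(w, Xv, d, h))^2)
    tr_sse <- c(tr_sse, st$sse); va_sse <- c(va_sse, val)
    if (val < best_val) {
      best_val <- val; best_w <- w; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= control$max_val_failures) {
        stop_reason <- "val_failures"; break
      }
    }
    if (st$sse <= control$min_sse) { stop_reason <- "converged"; break }
  }
  list(w = best_w, best_val_sse = best_val, epochs = epochs,
       stop_reason = stop_reason, train_sse = tr_sse, val_sse = va_sse)
}

#' Grid search over hidden-layer widths
#'
#' Fits [ann_lm()] for each candidate width (up to the architecture cap
#' of 8 hidden neurons) and returns the fit with the lowest validation
#' SSE.
#'
#' @inheritParams ann_lm
#' @param hidden Candidate widths (default `1:8` capped at 8).
#' @return The best `"ann_lm"` fit (with `n_hidden` recording the width).
#' @export
ann_lm_grid <- function(x, y, x_val = NULL, y_val = NULL, hidden = 1:8,
                        control = ann_control(), seed = NULL) {
  hidden <- hidden[hidden >= 1 & hidden <= 8]
  best <- NULL
  for (h in hidden) {
    fit <- ann_lm(x, y, x_val, y_val, n_hidden = h, control = control,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, 100 + h))
    if (is.null(best) || fit$best_val_sse < best$best_val_sse) best <- fit
  }
  best
}
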
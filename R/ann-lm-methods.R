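# S3 methods for "ann_lm" fits.

#' Predict from a fitted shallow network
#'
#' @param object An `"ann_lm"` fit.
#' @param newx Matrix of inputs (samples x channels) on the original
#'   scale; defaults to refusing silently missing data.
#' @param ... Unused.
#' @return Numeric predictions in the original target units.
#' @export
predict.ann_lm <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_inputs) {
    stopf("newx has %d columns; model expects %d", ncol(newx),
          object$n_inputs)
  }
  Xs <- minmax_apply(newx, object$scaling$x)
  ys <- forward_scaled(object$weights, Xs, object$n_inputs,
                       object$n_hidden)
  as.vector(minmax_invert_y(ys, object$scaling$y))
}

#' @export
print.ann_lm <- function(x, ...) {
  cat(sprintf("Shallow tanh network trained by Levenberg-Marquardt\n"))
  cat(sprintf("  inputs: %d, hidden neurons: %d, weights: %d\n",
              x$n_inputs, x$n_hidden, length(x$weights)))
  cat(sprintf("  epochs: %d (stop: %s), best validation SSE: %.4g\n",
              x$epochs_run, x$stop_reason, x$best_val_sse))
  invisible(x)
}

#' @export
summary.ann_lm <- function(object, ...) {
  res <- object$residuals_cal
  out <- list(n_inputs = object$n_inputs, n_hidden = object$n_hidden,
              epochs_run = object$epochs_run,
              stop_reason = object$stop_reason,
              best_val_sse = object$best_val_sse,
              cal_rmse = if (!is.null(res)) sqrt(mean(res^2)) else NA_real_,
              residual_sd = if (!is.null(res)) sd(res) else NA_real_)
  class(out) <- "summary.ann_lm"
  out
}

#' @export
print.summary.ann_lm <- function(x, ...) {
  cat("Levenberg-Marquardt shallow network\n")
  cat(sprintf("  architecture: %d-%d-1 (tanh / linear)\n", x$n_inputs,
              x$n_hidden))
  cat(sprintf("  epochs run: %d; stop reason: %s\n", x$epochs_run,
              x$stop_reason))
  cat(sprintf("  calibration RMSE: %.4g; best validation SSE: %.4g\n",
              x$cal_rmse, x$best_val_sse))
  invisible(x)
}

#' Extract network weights
#'
#' @param object An `"ann_lm"` fit.
#' @param unpacked Return the structured list (input weights, hidden
#'   biases, output weights, output bias) instead of the packed vector.
#' @param ... Unused.
#' @return Packed numeric vector or a list of weight blocks.
#' @export
coef.ann_lm <- function(object, unpacked = FALSE, ...) {
  if (!unpacked) return(object$weights)
  unpack_weights(object$weights, object$n_inputs, object$n_hidden)
}

#' @export
residuals.ann_lm <- function(object, ...) object$residuals_cal

#' Plot training and validation error trajectories
#'
#' @param x An `"ann_lm"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ann_lm <- function(x, ...) {
  if (length(x$train_sse) == 0) {
    message("no training trajectory recorded"); return(invisible(x))
  }
  graphics::matplot(cbind(x$train_sse, x$val_sse), type = "l", lty = 1,
                    col = c("black", "firebrick"), log = "y",
                    xlab = "epoch", ylab = "SSE (scaled space)", ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate responses from a fitted network
#'
#' Draws Gaussian responses around the network predictions using the
#' calibration residual standard deviation.
#'
#' @param object An `"ann_lm"` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newx Inputs to simulate at (default: calibration fitted values).
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.ann_lm <- function(object, nsim = 1, seed = NULL, newx = NULL,
                            ...) {
  mu <- if (is.null(newx)) object$fitted else predict(object, newx)
  sigma <- sd(object$residuals_cal %||% 0)
  with_seed(seed, {
    out <- replicate(nsim, rnorm(length(mu), mu, sigma))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' Serialize a fit to JSON
#'
#' Writes weights, scaling parameters, architecture and the training
#' trajectories to a JSON file so a fit can be archived with a run.
#'
#' @param fit An `"ann_lm"` fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ann_json <- function(fit, path) {
  payload <- list(n_inputs = fit$n_inputs, n_hidden = fit$n_hidden,
                  weights = fit$weights,
                  scaling = fit$scaling,
                  epochs_run = fit$epochs_run,
                  stop_reason = fit$stop_reason,
                  train_sse = fit$train_sse, val_sse = fit$val_sse)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
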
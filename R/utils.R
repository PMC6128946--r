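#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test filter lm lm.fit mad median pbeta
#'   predict pt quantile rbeta rnorm runif sd shapiro.test simulate var
#'   wilcox.test IQR residuals
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483629) + 1L
}

# Smooth positivity clamp: ~identity for x >> tau, smoothly positive near 0.
softplus <- function(x, tau = 1) {
  ifelse(x / tau > 30, x, tau * log1p(exp(x / tau)))
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
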
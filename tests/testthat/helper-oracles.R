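# Shared fixtures and independent oracles used across the suite.

# Lazily generated studies, shared across test files within a session.
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 11L) {
  key <- paste0("default_", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(study_design(),
                                          effect_config(), seed = seed)
  }
  .study_cache[[key]]
}

small_study <- function(seed = 7L) {
  key <- paste0("small_", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(
      study_design(n_repair_ponies = 3, n_control_ponies = 1,
                   joints_per_pony = 1, locations_per_joint = 8,
                   n_unreachable = 0),
      effect_config(n_light_contaminated = 1), seed = seed)
  }
  .study_cache[[key]]
}

# healthy latent state at the population centre
center_state <- function(water = 0.72) {
  list(water_fraction = water, collagen_density = 1,
       proteoglycan_density = 1, mineral_density = 1,
       scattering_slope = 0.5)
}

# Per-window least-squares cubic fit evaluated at the window centre:
# the direct (slow) definition of interior Savitzky-Golay smoothing.
sg_polyfit_oracle <- function(y, window, order = 3) {
  n <- length(y)
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    t <- (-h):h
    fit <- lm(y[(i - h):(i + h)] ~ poly(t, order, raw = TRUE))
    out[i] <- unname(predict(fit, data.frame(t = 0)))
  }
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all allocations of
# the pooled sample (tie-free inputs).
mw_enumeration_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_of <- function(x, y) sum(outer(x, y, `>`))
  u_all <- apply(idx, 2, function(k) u_of(pool[k], pool[-k]))
  u_obs <- u_of(a, b)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# Brute-force Spearman rho: classical d^2 formula when tie-free,
# hand-written Pearson product-moment on average ranks otherwise.
spearman_oracle <- function(x, y) {
  n <- length(x)
  if (!anyDuplicated(x) && !anyDuplicated(y)) {
    d <- rank(x) - rank(y)
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Type-7 quantile by hand (sort + linear interpolation).
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small random network fixture for Jacobian / LM-step tests
toy_net <- function(d = 3, h = 2, seed = 1) {
  set.seed(seed)
  list(w = rnorm(arthronirs:::n_weights(d, h), 0, 0.5),
       Xs = matrix(runif(5 * d, -1, 1), 5, d), d = d, h = h)
}

# central finite-difference prediction Jacobian of a packed-weight net
fd_jacobian_oracle <- function(w, Xs, n_hidden, h_step = 1e-5) {
  f <- function(wi) arthronirs:::forward_scaled(wi, Xs, ncol(Xs), n_hidden)
  J <- matrix(NA_real_, nrow(Xs), length(w))
  for (j in seq_along(w)) {
    wp <- w; wm <- w
    wp[j] <- wp[j] + h_step; wm[j] <- wm[j] - h_step
    J[, j] <- (f(wp) - f(wm)) / (2 * h_step)
  }
  J
}
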
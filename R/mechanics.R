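# Cartilage indentation mechanics: simulate stress-relaxation +
# sinusoidal indentation records from a standard-linear-solid ground
# truth, and recover the equilibrium and dynamic moduli from such
# records following the indentation protocol (four 5%-strain steps at
# 100%/s with 600 s holds, then 1 Hz sinusoidal loading at 1% strain
# amplitude, plane-ended cylindrical indenter d = 0.53 mm).

#' Indentation protocol parameters
#'
#' @param n_steps Stress-relaxation steps.
#' @param step_strain Strain increment per step.
#' @param ramp_rate Ramp velocity in strain/s (1.0 = 100%/s).
#' @param relax_time Hold time per step in seconds.
#' @param sine_freq Sinusoid frequency in Hz.
#' @param sine_amplitude Sinusoid strain amplitude.
#' @param sine_cycles Number of sinusoid cycles recorded.
#' @param indenter_diameter_um Indenter diameter in micrometres.
#' @return List of class `"indentation_protocol"`.
#' @export
indentation_protocol <- function(n_steps = 4L, step_strain = 0.05,
                                 ramp_rate = 1.0, relax_time = 600,
                                 sine_freq = 1.0, sine_amplitude = 0.01,
                                 sine_cycles = 10L,
                                 indenter_diameter_um = 530) {
  structure(list(n_steps = as.integer(n_steps), step_strain = step_strain,
                 ramp_rate = ramp_rate, relax_time = relax_time,
                 sine_freq = sine_freq, sine_amplitude = sine_amplitude,
                 sine_cycles = as.integer(sine_cycles),
                 indenter_diameter_um = indenter_diameter_um),
            class = "indentation_protocol")
}

# indenter cross-sectional area in m^2
indenter_area <- function(protocol) {
  pi * (protocol$indenter_diameter_um * 1e-6 / 2)^2
}

# strain history on a time grid for the protocol (ramp-and-hold steps
# followed by a sinusoid about the final strain)
strain_history <- function(protocol, dt = 0.005) {
  ramp_t <- protocol$step_strain / protocol$ramp_rate
  step_t <- ramp_t + protocol$relax_time
  t_steps <- seq(0, protocol$n_steps * step_t, by = dt)
  eps <- numeric(length(t_steps))
  for (k in seq_len(protocol$n_steps)) {
    t0 <- (k - 1) * step_t
    eps <- eps + pmin(pmax((t_steps - t0) / ramp_t, 0), 1) *
      protocol$step_strain
  }
  t_sin <- seq(dt, protocol$sine_cycles / protocol$sine_freq, by = dt) +
    max(t_steps)
  eps_sin <- protocol$n_steps * protocol$step_strain +
    protocol$sine_amplitude * sin(2 * pi * protocol$sine_freq *
                                    (t_sin - max(t_steps)))
  list(time = c(t_steps, t_sin), strain = c(eps, eps_sin),
       sine_start = max(t_steps))
}

#' Simulate an indentation record
#'
#' Standard-linear-solid (Zener) response to the stepped strain history
#' plus the sinusoidal segment, with configurable relative force noise.
#' The relaxation modulus is `E_eq_true + (E_inst - E_eq_true) *
#' exp(-t/tau)`; the measured indentation force applies the indenter
#' area and the `kappa / (1 - nu^2)` geometry conversion in reverse, so
#' that the analysis functions recover `E_eq_true` and the 1 Hz dynamic
#' modulus.
#'
#' @param E_eq_true Equilibrium Young's modulus, kPa.
#' @param E_inst Instantaneous modulus, kPa (`>= E_eq_true`).
#' @param tau Relaxation time constant, s.
#' @param protocol An [indentation_protocol()].
#' @param noise_sd Relative force noise SD (fraction of peak force).
#' @param kappa Indentation geometry correction factor (default 1; hook
#'   for Hayes-type aspect-ratio corrections).
#' @param sample_thickness_um Cartilage thickness, recorded as metadata.
#' @param dt Time resolution in seconds.
#' @param seed Optional seed.
#' @return List of class `"indentation_record"` with `time` (s),
#'   `force` (N), `strain`, `protocol`, `kappa`, `sine_start`.
#' @export
simulate_indentation <- function(E_eq_true, E_inst = 3 * E_eq_true,
                                 tau = 20,
                                 protocol = indentation_protocol(),
                                 noise_sd = 0, kappa = 1,
                                 sample_thickness_um = 1000,
                                 dt = 0.005, seed = NULL) {
  if (E_eq_true <= 0) stopf("E_eq_true must be positive")
  if (E_inst < E_eq_true) stopf("E_inst must be >= E_eq_true")
  with_seed(seed, {
    hist <- strain_history(protocol, dt)
    t <- hist$time; eps <- hist$strain
    n <- length(t)
    # recursive exponential-kernel convolution for the Zener solid:
    # sigma = E_eq * eps + q,  dq/dt = -q/tau + (E_inst - E_eq) deps/dt
    decay <- exp(-dt / tau)
    dE <- E_inst - E_eq_true
    deps <- c(0, diff(eps))
    q <- as.vector(stats::filter(dE * deps, decay, method = "recursive"))
    sigma_kpa <- E_eq_true * eps + q          # kPa (material stress)
    # equilibrium branch measured with nu = 0.1: indentation stress =
    # kappa * E / (1 - nu^2) * eps, with nu depending on loading rate;
    # the sinusoidal (fast) branch uses nu = 0.5. Blend by segment.
    nu_eq <- 0.1; nu_dyn <- 0.5
    conv <- ifelse(t <= hist$sine_start, kappa / (1 - nu_eq^2),
                   kappa / (1 - nu_dyn^2))
    force <- sigma_kpa * 1e3 * conv * indenter_area(protocol)  # N
    if (noise_sd > 0) {
      force <- force + rnorm(n, 0, noise_sd * max(abs(force)))
    }
    structure(list(time = t, force = force, strain = eps,
                   protocol = protocol, kappa = kappa,
                   sample_thickness_um = sample_thickness_um,
                   sine_start = hist$sine_start),
              class = "indentation_record")
  })
}

# equilibrium stress (kPa) per relaxation step: mean measured stress
# over the final fraction of each hold window
step_equilibrium_stress <- function(record, window_frac = 0.10) {
  pr <- record$protocol
  ramp_t <- pr$step_strain / pr$ramp_rate
  step_t <- ramp_t + pr$relax_time
  area <- indenter_area(pr)
  vapply(seq_len(pr$n_steps), function(k) {
    t_end <- k * step_t
    sel <- record$time >= t_end - window_frac * pr$relax_time &
      record$time <= t_end
    mean(record$force[sel]) / area / 1e3  # kPa
  }, numeric(1))
}

#' Equilibrium modulus from a stress-relaxation record
#'
#' Per-step equilibrium stress is the mean force over the final 10% of
#' each 600 s hold divided by the indenter area. The linear region is
#' the contiguous subset of at least two steps whose equilibrium
#' stress-strain fit maximises R-squared; the modulus is that slope
#' converted with Poisson's ratio 0.1 and the geometry factor kappa.
#'
#' @param record An `"indentation_record"`.
#' @param nu Poisson's ratio (0.1 for the equilibrium branch).
#' @param kappa Geometry correction factor; defaults to the record's.
#' @param window_frac Fraction of each hold used as the equilibrium
#'   window.
#' @return Equilibrium modulus in kPa, with attributes `r_squared` and
#'   `steps_used`.
#' @export
equilibrium_modulus <- function(record, nu = 0.1, kappa = NULL,
                                window_frac = 0.10) {
  pr <- record$protocol
  if (pr$n_steps < 2) stopf("need >= 2 relaxation steps")
  kappa <- kappa %||% record$kappa %||% 1
  sig <- step_equilibrium_stress(record, window_frac)
  eps <- seq_len(pr$n_steps) * pr$step_strain
  if (any(diff(sig) < 0)) {
    warning("non-monotone equilibrium stresses; fit returned anyway")
  }
  # best contiguous subset (size >= 2) by R^2; a 2-point fit has R^2 = 1,
  # so prefer the longest subset among those within numerical tolerance
  best <- NULL
  for (len in pr$n_steps:2) {
    for (s in 1:(pr$n_steps - len + 1)) {
      idx <- s:(s + len - 1)
      fit <- lm(sig[idx] ~ eps[idx])
      r2 <- summary(fit)$r.squared
      if (is.null(best) || r2 > best$r2 + 1e-6) {
        best <- list(idx = idx, slope = coef(fit)[2], r2 = r2)
      }
    }
  }
  e_eq <- unname(best$slope) * (1 - nu^2) / kappa
  structure(e_eq, r_squared = best$r2, steps_used = best$idx)
}

#' Dynamic modulus from the sinusoidal loading segment
#'
#' Fits a sinusoid at the protocol frequency to the stress in the
#' sinusoidal segment; the dynamic modulus is the stress amplitude over
#' the strain amplitude (phase-invariant), converted with Poisson's
#' ratio 0.5 and kappa, reported in MPa.
#'
#' @param record An `"indentation_record"`.
#' @param nu Poisson's ratio (0.5 for the dynamic branch).
#' @param kappa Geometry correction; defaults to the record's.
#' @param residual_tol Warn if the relative sinusoid-fit residual
#'   exceeds this.
#' @return Dynamic modulus in MPa with attribute `fit_residual`.
#' @export
dynamic_modulus <- function(record, nu = 0.5, kappa = NULL,
                            residual_tol = 0.05) {
  pr <- record$protocol
  kappa <- kappa %||% record$kappa %||% 1
  sel <- record$time > record$sine_start
  if (sum(sel) < 10 || pr$sine_cycles < 5) {
    stopf("sinusoidal segment with >= 5 cycles required")
  }
  t <- record$time[sel] - record$sine_start
  sig <- record$force[sel] / indenter_area(pr) / 1e3  # kPa
  w <- 2 * pi * pr$sine_freq
  X <- cbind(1, sin(w * t), cos(w * t))
  cf <- lm.fit(X, sig)$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  resid_rel <- sqrt(mean((sig - X %*% cf)^2)) / amp
  if (resid_rel > residual_tol) {
    warning(sprintf("sinusoid fit residual %.1f%% exceeds tolerance",
                    100 * resid_rel))
  }
  e_dyn_kpa <- amp / pr$sine_amplitude * (1 - nu^2) / kappa
  structure(e_dyn_kpa / 1e3, fit_residual = resid_rel)
}

#' Write an indentation record to CSV with a JSON protocol sidecar
#'
#' @param record An `"indentation_record"`.
#' @param path CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_indentation_csv <- function(record, path) {
  write.csv(data.frame(time_s = record$time, force_N = record$force,
                       strain = record$strain),
            path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(c(unclass(record$protocol),
                         list(kappa = record$kappa,
                              sample_thickness_um = record$sample_thickness_um)),
                       side, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
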
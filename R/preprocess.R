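# Spectral preprocessing: per-arm Savitzky-Golay smoothing, region
# trimming and arm merging, the probe-contact area statistic, spectrum
# and location exclusion, and the arthroscopic/in-vitro coefficient of
# variation.

# Smoothing-window defaults per parameter family: (arm-a, arm-b).
sg_windows <- function(parameter_family = c("cartilage", "bone")) {
  switch(match.arg(parameter_family),
         cartilage = c(arm_a = 25L, arm_b = 13L),
         bone = c(arm_a = 45L, arm_b = 13L))
}

# Parameter family per modelled reference parameter.
parameter_family <- function(parameter) {
  fam <- c(E_eq = "cartilage", E_dyn = "cartilage",
           plate_BV = "bone", plate_BMD = "bone", plate_thickness = "bone",
           trab_BV = "bone", trab_BMD = "bone", trab_thickness = "bone",
           SMI = "bone")
  out <- fam[parameter]
  if (anyNA(out)) stopf("unknown parameter: %s",
                        paste(parameter[is.na(out)], collapse = ", "))
  unname(out)
}

# Dense linear smoothing operator for a length-n signal: interior points
# use the standard central Savitzky-Golay projection; edge points use a
# shrunken window (all available points within the half-window, no
# padding), fitting a polynomial of degree min(order, points - 1).
# Cached per (n, window, order).
sg_operator_cache <- new.env(parent = emptyenv())

sg_operator <- function(n, window, order = 3) {
  key <- sprintf("%d_%d_%d", n, window, order)
  hit <- sg_operator_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  row_weights <- function(idx, i, deg) {
    Ad <- outer(idx - i, 0:deg, `^`)
    # weights w s.t. fitted value at x = i equals w %*% y[idx]
    (solve(crossprod(Ad)) %*% t(Ad))[1, ]
  }
  interior_w <- row_weights((-h):h + 0, 0, order)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      S[i, lo:hi] <- interior_w
    } else {
      deg <- min(order, hi - lo)
      S[i, lo:hi] <- row_weights(lo:hi, i, deg)
    }
  }
  sg_operator_cache[[key]] <- S
  S
}

#' Savitzky-Golay smoothing
#'
#' Third-order (by default) Savitzky-Golay smoothing on a uniform grid.
#' Interior points reproduce the classical central-window polynomial
#' fit; edge points are fitted on the shrunken window of available
#' points (no padding), so polynomial signals of degree `<= order` are
#' reproduced exactly everywhere.
#'
#' @param intensity Numeric vector (a single spectrum) or a matrix with
#'   one spectrum per row.
#' @param window Odd window length, `order < window <= length`.
#' @param order Polynomial order (default 3).
#' @return Smoothed vector/matrix of the same shape.
#' @examples
#' sg_smooth(sin(seq(0, 3, length.out = 50)), window = 13)
#' @export
sg_smooth <- function(intensity, window, order = 3) {
  n <- if (is.matrix(intensity)) ncol(intensity) else length(intensity)
  if (window %% 2 == 0) stopf("window must be odd")
  if (window <= order) stopf("window must exceed the polynomial order")
  if (window > n) stopf("window (%d) exceeds signal length (%d)", window, n)
  S <- sg_operator(n, window, order)
  if (is.matrix(intensity)) intensity %*% t(S) else as.vector(S %*% intensity)
}

# Merged wavelength grid and per-arm channel indices for a region.
# The arms overlap on 1.0-1.1 um; arm a supplies channels < 1.0 um, arm
# b supplies channels >= 1.0 um, so each wavelength has one source.
merge_plan <- function(region) {
  la <- arm_a_grid(); lb <- arm_b_grid()
  eps <- 1e-9
  ia <- which(la >= region[1] - eps & la < 1.0 - eps)
  ib <- which(lb >= 1.0 - eps & lb < min(region[2], 1.90) - eps)
  if (length(ia) + length(ib) == 0) stopf("region outside the study grids")
  list(ia = ia, ib = ib, wavelengths = c(la[ia], lb[ib]))
}

#' Preprocess a raw spectrum for a parameter family
#'
#' Smooths each spectrometer arm with the family's Savitzky-Golay
#' windows (cartilage: 25 and 13 points; bone: 45 and 13 points; order
#' 3), merges the arms at 1.0 um (arm a supplies channels below, arm b
#' at or above), and trims to the requested region. The water-saturated
#' region at and above 1.9 um is always discarded.
#'
#' @param parameter_family `"cartilage"` or `"bone"`.
#' @param raw A `"raw_spectrum"` (see [simulate_spectrum()]).
#' @param region Length-2 numeric, either `c(0.40, 1.90)` or
#'   `c(0.75, 1.90)` um.
#' @return A list of class `"processed_spectrum"` with `wavelengths`,
#'   `intensity`, `variant`, `region`, `windows`, `metadata`.
#' @export
preprocess_for <- function(parameter_family = c("cartilage", "bone"), raw,
                           region = c(0.75, 1.90)) {
  parameter_family <- match.arg(parameter_family)
  if (!identical(length(region), 2L) && length(region) != 2) {
    stopf("region must be a length-2 numeric")
  }
  if (!isTRUE(all.equal(region, c(0.40, 1.90))) &&
      !isTRUE(all.equal(region, c(0.75, 1.90)))) {
    stopf("region must be 0.40-1.90 or 0.75-1.90 um")
  }
  if (!isTRUE(all.equal(raw$arm_a_wavelengths, arm_a_grid())) ||
      !isTRUE(all.equal(raw$arm_b_wavelengths, arm_b_grid()))) {
    stopf("raw spectrum grids do not match the study manifest")
  }
  w <- sg_windows(parameter_family)
  sa <- sg_smooth(raw$arm_a_intensity, w[["arm_a"]])
  sb <- sg_smooth(raw$arm_b_intensity, w[["arm_b"]])
  plan <- merge_plan(region)
  structure(list(wavelengths = plan$wavelengths,
                 intensity = c(sa[plan$ia], sb[plan$ib]),
                 variant = parameter_family, region = region, windows = w,
                 metadata = raw$metadata),
            class = "processed_spectrum")
}

# Indices of the arm-a contact-QC region [0.42, 0.75] um, with the
# channels nearest the endpoints.
contact_region_idx <- function() {
  la <- arm_a_grid()
  idx <- which(la >= 0.42 - 1e-9 & la <= 0.75 + 1e-9)
  if (length(idx) < 3) stopf("arm a does not cover 0.42-0.75 um")
  list(idx = idx,
       i1 = idx[which.min(abs(la[idx] - 0.42))],
       i2 = idx[which.min(abs(la[idx] - 0.75))])
}

#' Probe-contact quality area statistic
#'
#' Fits a straight line through the (smoothed) spectrum's values at the
#' channels nearest 0.42 and 0.75 um and integrates the absolute
#' deviation between spectrum and line over that region (trapezoidal
#' rule). Poor probe contact and arthroscope-light contamination both
#' bow the visible region away from the chord, inflating the area;
#' spectra are ranked by it and the worst repeats discarded.
#'
#' @param raw A `"raw_spectrum"`, or a numeric vector of arm-a
#'   intensities on the study grid.
#' @param smoothed Logical; smooth arm a (25-point window) before
#'   computing the statistic (the statistic is defined on smoothed
#'   intensities).
#' @return The area (intensity x um), a non-negative scalar.
#' @export
contact_area <- function(raw, smoothed = TRUE) {
  y <- if (inherits(raw, "raw_spectrum")) raw$arm_a_intensity else as.numeric(raw)
  if (length(y) != length(arm_a_grid())) {
    stopf("arm-a intensities must be on the study grid")
  }
  if (smoothed) y <- sg_smooth(y, 25L)
  cr <- contact_region_idx()
  la <- arm_a_grid()
  x <- la[cr$idx]
  line <- y[cr$i1] + (y[cr$i2] - y[cr$i1]) *
    (x - la[cr$i1]) / (la[cr$i2] - la[cr$i1])
  trapz(x, abs(y[cr$idx] - line))
}

# Vectorised contact areas for a matrix of arm-a spectra (rows).
# Smoothing is applied on a padded sub-grid around the QC region so the
# interior weights match full-spectrum smoothing.
contact_area_matrix <- function(A, smoothed = TRUE, window = 25L) {
  la <- arm_a_grid()
  cr <- contact_region_idx()
  h <- (window - 1L) %/% 2L
  lo <- max(1L, min(cr$idx) - h); hi <- min(length(la), max(cr$idx) + h)
  sub <- A[, lo:hi, drop = FALSE]
  if (smoothed) sub <- sg_smooth(sub, window)
  idx <- cr$idx - lo + 1L
  i1 <- cr$i1 - lo + 1L; i2 <- cr$i2 - lo + 1L
  x <- la[cr$idx]
  t1 <- (x - la[cr$i1]) / (la[cr$i2] - la[cr$i1])
  out <- numeric(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    y <- sub[r, ]
    line <- y[i1] + (y[i2] - y[i1]) * t1
    out[r] <- trapz(x, abs(y[idx] - line))
  }
  out
}

#' Retain the best repeat spectra by contact area
#'
#' Keeps the `keep` repeats with the smallest contact-quality area
#' (best probe contact); ties are broken in favour of earlier repeat
#' indices. With the study defaults this drops 7 of the 15 arthroscopic
#' repeats at every location.
#'
#' @param areas Numeric vector of contact areas.
#' @param repeat_index Integer repeat indices (defaults to 1..n).
#' @param keep Number of spectra to retain (default 8).
#' @return Integer positions (into `areas`) of the retained spectra, in
#'   increasing area order.
#' @export
select_best_spectra <- function(areas, repeat_index = seq_along(areas),
                                keep = 8L) {
  if (length(areas) < keep) {
    stopf("need at least %d spectra, got %d", keep, length(areas))
  }
  ord <- order(areas, repeat_index)
  ord[seq_len(keep)]
}

#' Contamination threshold from a study-wide area distribution
#'
#' Robust outlier rule: 3 robust SDs (median absolute deviation scaled
#' for normal consistency) above the median of the supplied study-wide
#' contact-area distribution. For flagging light-contaminated
#' arthroscopic locations the reference distribution is the pooled
#' arthroscopic per-spectrum areas: every arthroscopic spectrum carries
#' a baseline arthroscope-light contribution, so the in-vitro areas sit
#' on a different scale and a handful of heavily contaminated locations
#' cannot move a median/MAD rule.
#'
#' @param areas Contact areas of the study-wide reference distribution.
#' @param n_sd Number of robust SDs above the median.
#' @return Scalar threshold.
#' @export
contamination_threshold <- function(areas, n_sd = 3) {
  median(areas) + n_sd * mad(areas)
}

#' Flag a location as arthroscope-light contaminated
#'
#' A location is flagged when the median contact area of its retained
#' repeats exceeds the threshold; flagged locations are excluded from
#' arthroscopic evaluation.
#'
#' @param retained_areas Contact areas of the retained repeats.
#' @param threshold Scalar threshold (see [contamination_threshold()]);
#'   `Inf` never flags.
#' @return Logical.
#' @export
flag_contaminated_location <- function(retained_areas, threshold) {
  median(retained_areas) > threshold
}

#' Coefficient of variation between paired spectra
#'
#' Per-channel coefficient of variation of the two paired intensities
#' (population SD of the pair divided by its mean), averaged over
#' channels in the requested region and expressed in percent. Channels
#' with non-positive mean are skipped with a message.
#'
#' @param a,b Two `"processed_spectrum"` objects on a common grid (e.g.
#'   the mean arthroscopic and mean in-vitro spectrum of a location).
#' @param region Wavelength window (default 0.75-1.9 um).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(a, b, region = c(0.75, 1.90)) {
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stopf("spectra are not on a common channel grid")
  }
  keep <- a$wavelengths >= region[1] - 1e-9 & a$wavelengths < region[2] - 1e-9
  if (!any(keep)) stopf("region outside the processed grid")
  x <- a$intensity[keep]; y <- b$intensity[keep]
  m <- (x + y) / 2
  ok <- m > 0
  if (!all(ok)) message(sum(!ok), " channels with non-positive mean skipped")
  # population SD of a pair {x, y} is |x - y| / 2
  100 * mean(abs(x[ok] - y[ok]) / (2 * m[ok]))
}

#' Preprocess a synthetic study for modelling
#'
#' Runs the full preprocessing chain on a generated study for one
#' parameter family and region: computes contact areas for every
#' arthroscopic repeat, retains the best 8 per location, flags
#' light-contaminated locations against the study-wide arthroscopic
#' area distribution,
#' averages the in-vitro repeats per location, then smooths, merges and
#' trims everything to a single channel matrix per modality.
#'
#' @param study A `"nirs_study"` from [generate_study()].
#' @param parameter_family `"cartilage"` or `"bone"`.
#' @param region `c(0.75, 1.90)` or `c(0.40, 1.90)`.
#' @param keep Retained arthroscopic repeats per location (default 8).
#' @return A list of class `"nirs_proc"`: `wavelengths`; `X_invitro`
#'   (locations x channels, repeat-averaged); `invitro_meta`;
#'   `X_arthro` (retained repeats x channels) with `arthro_meta`;
#'   `qc` (per arthroscopic location: median retained area, retained
#'   repeat indices, contamination flag); `variant`, `region`.
#' @export
preprocess_study <- function(study, parameter_family = c("cartilage", "bone"),
                             region = c(0.75, 1.90), keep = 8L) {
  parameter_family <- match.arg(parameter_family)
  stopifnot(inherits(study, "nirs_study"))
  meta <- study$meta
  iv <- which(meta$modality == "in_vitro")
  ar <- which(meta$modality == "arthroscopic")

  areas <- numeric(nrow(meta))
  areas[iv] <- contact_area_matrix(study$arm_a[iv, , drop = FALSE])
  if (length(ar) > 0) {
    areas[ar] <- contact_area_matrix(study$arm_a[ar, , drop = FALSE])
  }
  thr <- if (length(ar) > 0) contamination_threshold(areas[ar]) else Inf

  # per-location averaging (in vitro) / retention (arthroscopic)
  iv_ids <- unique(meta$loc_id[iv])
  Aiv <- rowsum(study$arm_a[iv, , drop = FALSE], meta$loc_id[iv], reorder = FALSE)
  Biv <- rowsum(study$arm_b[iv, , drop = FALSE], meta$loc_id[iv], reorder = FALSE)
  cnt <- as.vector(table(factor(meta$loc_id[iv], levels = rownames(Aiv))))
  Aiv <- Aiv / cnt; Biv <- Biv / cnt
  iv_meta <- meta[iv, ][match(rownames(Aiv), meta$loc_id[iv]),
                        c("pony", "joint", "location", "group",
                          "distance_class", "loc_id")]
  rownames(iv_meta) <- NULL

  qc <- NULL; ar_keep <- integer(0)
  if (length(ar) > 0) {
    ar_ids <- unique(meta$loc_id[ar])
    qc_rows <- vector("list", length(ar_ids))
    for (k in seq_along(ar_ids)) {
      rows <- ar[meta$loc_id[ar] == ar_ids[k]]
      sel <- select_best_spectra(areas[rows], meta$repeat_index[rows],
                                 keep = keep)
      kept <- rows[sel]
      ar_keep <- c(ar_keep, kept)
      qc_rows[[k]] <- data.frame(
        loc_id = ar_ids[k],
        median_area = median(areas[kept]),
        retained_repeats = paste(meta$repeat_index[kept], collapse = ","),
        flagged = flag_contaminated_location(areas[kept], thr))
    }
    qc <- do.call(rbind, qc_rows)
  }

  w <- sg_windows(parameter_family)
  plan <- merge_plan(region)
  proc_mat <- function(A, B) {
    cbind(sg_smooth(A, w[["arm_a"]])[, plan$ia, drop = FALSE],
          sg_smooth(B, w[["arm_b"]])[, plan$ib, drop = FALSE])
  }
  X_iv <- proc_mat(Aiv, Biv)
  X_ar <- NULL; ar_meta <- NULL
  if (length(ar_keep) > 0) {
    X_ar <- proc_mat(study$arm_a[ar_keep, , drop = FALSE],
                     study$arm_b[ar_keep, , drop = FALSE])
    ar_meta <- meta[ar_keep, c("pony", "joint", "location", "group",
                               "distance_class", "loc_id", "repeat_index")]
    ar_meta$area <- areas[ar_keep]
    rownames(ar_meta) <- NULL
  }
  structure(list(wavelengths = plan$wavelengths,
                 X_invitro = X_iv, invitro_meta = iv_meta,
                 X_arthro = X_ar, arthro_meta = ar_meta,
                 qc = qc, area_threshold = thr,
                 variant = parameter_family, region = region),
            class = "nirs_proc")
}
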
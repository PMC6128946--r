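# Greedy forward selection over wavelength channels, with the three
# model-variant criteria: Model 1 (0.75-1.90 um, criterion = mean of
# test and arthroscopic NRMSE), Model 2 (0.75-1.90 um, test NRMSE) and
# Model 3 (0.40-1.90 um, test NRMSE).

#' Model variant definitions
#'
#' @param name `"Model1"`, `"Model2"` or `"Model3"`.
#' @return List with `name`, `region` (um) and `criterion`
#'   (`"test_plus_arthro"` for Model 1, `"test_only"` otherwise).
#' @export
model_variant <- function(name = c("Model1", "Model2", "Model3")) {
  name <- match.arg(name)
  switch(name,
         Model1 = list(name = name, region = c(0.75, 1.90),
                       criterion = "test_plus_arthro"),
         Model2 = list(name = name, region = c(0.75, 1.90),
                       criterion = "test_only"),
         Model3 = list(name = name, region = c(0.40, 1.90),
                       criterion = "test_only"))
}

#' Candidate wavelength grid
#'
#' Every `stride`-th processed channel within the region, deterministic.
#'
#' @param wavelengths Processed channel wavelengths (um).
#' @param region Length-2 interval (um).
#' @param stride Keep every `stride`-th channel (default 4: after
#'   smoothing, adjacent channels carry nearly identical information).
#' @return Integer indices into `wavelengths`.
#' @export
candidate_grid <- function(wavelengths, region = c(0.75, 1.90),
                           stride = 4L) {
  if (stride < 1) stopf("stride must be >= 1")
  idx <- which(wavelengths >= region[1] - 1e-9 &
                 wavelengths < region[2] - 1e-9)
  if (length(idx) == 0) stopf("no channels inside the region")
  idx[seq(1, length(idx), by = stride)]
}

#' Combined selection criterion for arthroscopy-aware models
#'
#' The arithmetic mean of the test-set NRMSE and the arthroscopic
#' NRMSE, both in percent: a scale-free, equally weighted compromise
#' between in-vitro generalisation and arthroscopic robustness.
#'
#' @param nrmse_test,nrmse_arthro NRMSE values in percent.
#' @return Scalar criterion (lower is better).
#' @export
combined_criterion <- function(nrmse_test, nrmse_arthro) {
  if (length(nrmse_test) == 0 || length(nrmse_arthro) == 0) {
    stopf("both criterion sets must be nonempty")
  }
  mean(c(nrmse_test, nrmse_arthro))
}

#' Greedy forward variable selection
#'
#' Starting from the empty set, repeatedly adds the candidate that
#' minimises `criterion_fn` on the augmented subset. Additions continue
#' (always taking the round's best candidate) until the budget is
#' exhausted or `patience` consecutive additions have failed to improve
#' the best criterion seen; the best-so-far prefix is returned.
#' Candidates for which the criterion is non-finite are skipped.
#'
#' @param candidates Vector of candidate identifiers (e.g. channel
#'   indices).
#' @param criterion_fn Function mapping a subset of `candidates` to a
#'   scalar (lower is better).
#' @param budget Maximum number of selected variables.
#' @param patience Consecutive non-improving additions tolerated.
#' @return List of class `"forward_selection"`: `selected` (best
#'   prefix, in selection order), `criterion` (criterion at the best
#'   prefix), `trajectory` (criterion after each accepted addition),
#'   `path` (all additions, including the non-improving tail).
#' @export
forward_select <- function(candidates, criterion_fn, budget = 220L,
                           patience = 10L) {
  if (length(candidates) == 0) stopf("candidates must be nonempty")
  chosen <- c()
  remaining <- candidates
  trajectory <- numeric(0)
  best_crit <- Inf
  best_len <- 0L
  fails <- 0L
  while (length(chosen) < budget && length(remaining) > 0) {
    crits <- vapply(remaining, function(cand) {
      val <- tryCatch(criterion_fn(c(chosen, cand)),
                      error = function(e) NA_real_)
      if (!is.finite(val)) NA_real_ else val
    }, numeric(1))
    if (all(is.na(crits))) {
      message("all remaining candidates returned non-finite criteria")
      break
    }
    k <- which.min(crits)
    chosen <- c(chosen, remaining[k])
    remaining <- remaining[-k]
    trajectory <- c(trajectory, crits[k])
    if (crits[k] < best_crit) {
      best_crit <- crits[k]; best_len <- length(chosen); fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= patience) break
    }
  }
  structure(list(selected = chosen[seq_len(best_len)],
                 criterion = best_crit,
                 trajectory = trajectory[seq_len(best_len)],
                 path = chosen, path_criteria = trajectory),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection: %d variables (criterion %.4g; %d tried)\n",
              length(x$selected), x$criterion, length(x$path)))
  invisible(x)
}

#' Histogram of selected wavelengths
#'
#' Bins selected channel positions into fixed-width bins of `bin`
#' channels (default 10), mirroring the selected-wavelength histograms
#' used to read which overtone bands drive a model.
#'
#' @param selected_idx Selected channel indices.
#' @param wavelengths Full processed wavelength vector (um).
#' @param bin Bin width in channels.
#' @return Data frame with `bin_start_um`, `bin_end_um`, `count`.
#' @export
selection_histogram <- function(selected_idx, wavelengths, bin = 10L) {
  starts <- seq(1L, length(wavelengths), by = bin)
  counts <- vapply(starts, function(s) {
    sum(selected_idx >= s & selected_idx < s + bin)
  }, integer(1))
  data.frame(bin_start_um = wavelengths[starts],
             bin_end_um = wavelengths[pmin(starts + bin - 1L,
                                           length(wavelengths))],
             count = counts)
}

#' Select wavelengths and train the final model for one parameter
#'
#' Runs greedy forward selection over the processed channel grid for a
#' given reference parameter and model variant, using a reduced
#' training budget per candidate (small fixed hidden width, capped
#' epochs, one restart), then retrains the final subset with the full
#' budget and a hidden-width grid search.
#'
#' @param proc A `"nirs_proc"` object (see [preprocess_study()]) whose
#'   region matches the variant.
#' @param y_by_loc Named numeric: reference values indexed by `loc_id`.
#' @param split A split from [split_by_pony()].
#' @param variant A [model_variant()].
#' @param stride,budget,patience Candidate-grid and selection controls.
#' @param search_control [ann_control()] for per-candidate fits.
#' @param final_control [ann_control()] for the final refit.
#' @param search_hidden Hidden width during the search.
#' @param final_hidden Hidden-width grid for the final refit.
#' @param seed Integer seed.
#' @return List of class `"wavelength_selection"`: `selection`
#'   (a `"forward_selection"`), `selected_wavelengths`, `fit` (final
#'   `"ann_lm"`), `variant`, `n_variables`.
#' @export
select_wavelengths <- function(proc, y_by_loc, split, variant,
                               stride = 4L, budget = 220L, patience = 10L,
                               search_control = ann_control(
                                 max_epochs = 20L, n_restarts = 1L),
                               final_control = ann_control(
                                 max_epochs = 150L, n_restarts = 2L),
                               search_hidden = 2L, final_hidden = 1:4,
                               seed = 1L) {
  stopifnot(inherits(proc, "nirs_proc"))
  if (!isTRUE(all.equal(proc$region, variant$region))) {
    stopf("processed region does not match variant %s", variant$name)
  }
  ds <- assemble_sets(proc, y_by_loc, split)
  cand <- candidate_grid(proc$wavelengths, variant$region, stride)
  rng <- diff(range(ds$y_all))
  use_arthro <- identical(variant$criterion, "test_plus_arthro")
  if (use_arthro && is.null(ds$X_arthro)) {
    stopf("variant %s needs arthroscopic data", variant$name)
  }
  crit_fn <- function(subset) {
    fit <- ann_lm(ds$X_cal[, subset, drop = FALSE], ds$y_cal,
                  ds$X_val[, subset, drop = FALSE], ds$y_val,
                  n_hidden = search_hidden, control = search_control,
                  seed = derive_seed(seed, 7 + length(subset)))
    pt <- predict(fit, ds$X_test[, subset, drop = FALSE])
    nr_test <- nrmse(ds$y_test, pt, rng)
    if (!use_arthro) return(nr_test)
    pa <- predict(fit, ds$X_arthro[, subset, drop = FALSE])
    agg <- aggregate_by_location(pa, ds$arthro_loc)
    ok <- !is.na(agg$pred)
    nr_ar <- nrmse(ds$y_arthro[agg$loc_id][ok], agg$pred[ok], rng)
    combined_criterion(nr_test, nr_ar)
  }
  sel <- forward_select(cand, crit_fn, budget = budget, patience = patience)
  idx <- sel$selected
  fit <- ann_lm_grid(ds$X_cal[, idx, drop = FALSE], ds$y_cal,
                     ds$X_val[, idx, drop = FALSE], ds$y_val,
                     hidden = final_hidden, control = final_control,
                     seed = derive_seed(seed, 991))
  structure(list(selection = sel,
                 selected_wavelengths = proc$wavelengths[idx],
                 selected_idx = idx, fit = fit, variant = variant,
                 n_variables = length(idx)),
            class = "wavelength_selection")
}

# Build calibration/validation/test matrices (in vitro) and the
# retained arthroscopic spectra for one processed study + split.
assemble_sets <- function(proc, y_by_loc, split) {
  m <- proc$invitro_meta
  y <- y_by_loc[m$loc_id]
  set <- split$assignment[match(m$pony, split$assignment$pony), "set"]
  keep <- !is.na(y)
  pick <- function(s) which(keep & set == s)
  ical <- pick("cal"); ival <- pick("val"); itest <- pick("test")
  out <- list(
    X_cal = proc$X_invitro[ical, , drop = FALSE], y_cal = y[ical],
    X_val = proc$X_invitro[ival, , drop = FALSE], y_val = y[ival],
    X_test = proc$X_invitro[itest, , drop = FALSE], y_test = y[itest],
    y_all = y[keep], y_by_loc = y_by_loc)
  if (!is.null(proc$X_arthro)) {
    am <- proc$arthro_meta
    unflagged <- proc$qc$loc_id[!proc$qc$flagged]
    sel <- am$loc_id %in% unflagged & !is.na(y_by_loc[am$loc_id])
    out$X_arthro <- proc$X_arthro[sel, , drop = FALSE]
    out$arthro_loc <- am$loc_id[sel]
    out$y_arthro <- y_by_loc
  }
  out
}
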
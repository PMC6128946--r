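# End-to-end orchestration: subject-level splitting, run configuration,
# and the full simulate -> preprocess -> select/train -> evaluate ->
# report pipeline.

#' Split a study into calibration / validation / test by pony
#'
#' Assignment is at pony (subject) granularity so no pony ever spans
#' groups: no spectral or reference information can leak between sets.
#' Pony counts follow the fractions (default 60/30/10); control ponies
#' are distributed over calibration and validation only, and the test
#' pony is drawn from the repair ponies, preferring ponies with all
#' locations reachable (the emulated study's test group has the full
#' complement of 24 locations).
#'
#' @param references The per-location reference table of a study (or
#'   any data frame with `pony`, `group`, `loc_id` columns).
#' @param fractions Length-3 fractions summing to 1 (cal, val, test).
#' @param seed Integer seed; the assignment is deterministic under it.
#' @return List of class `"pony_split"`: `assignment` (data frame
#'   `pony`, `group`, `set`) and `counts`.
#' @export
split_by_pony <- function(references, fractions = c(0.6, 0.3, 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  ponies <- unique(references[, c("pony", "group")])
  n <- nrow(ponies)
  if (n < 3) stopf("need at least 3 ponies to split")
  n_test <- max(1L, round(fractions[3] * n))
  n_cal <- round(fractions[1] * n)
  n_val <- n - n_cal - n_test
  if (n_val < 1) { n_val <- 1L; n_cal <- n - n_test - 1L }
  repair <- ponies$pony[ponies$group == "repair"]
  control <- ponies$pony[ponies$group == "control"]
  if (length(repair) < n_test) {
    stopf("not enough repair ponies for the test set")
  }
  with_seed(seed, {
    # test pony: repair ponies with the most reachable locations first
    n_loc <- as.numeric(table(references$pony)[repair])
    ord <- order(-n_loc, runif(length(repair)))  # seeded tie-break
    test_p <- repair[ord][seq_len(n_test)]
    # control ponies split over cal/val in proportion to the fractions
    c_cal <- round(length(control) * fractions[1] /
                     (fractions[1] + fractions[2]))
    ctrl <- if (length(control)) sample(control) else character(0)
    ctrl_cal <- head(ctrl, c_cal)
    ctrl_val <- setdiff(ctrl, ctrl_cal)
    rep_left <- sample(setdiff(repair, test_p))
    r_cal <- n_cal - length(ctrl_cal)
    if (r_cal < 0 || r_cal > length(rep_left)) {
      stopf("impossible allocation for the requested fractions")
    }
    rep_cal <- head(rep_left, r_cal)
    rep_val <- setdiff(rep_left, rep_cal)
    assignment <- rbind(
      data.frame(pony = c(rep_cal, ctrl_cal), set = "cal"),
      data.frame(pony = c(rep_val, ctrl_val), set = "val"),
      data.frame(pony = test_p, set = "test"))
    assignment$group <- ponies$group[match(assignment$pony, ponies$pony)]
    assignment <- assignment[order(assignment$pony), c("pony", "group", "set")]
    rownames(assignment) <- NULL
    structure(list(assignment = assignment,
                   counts = table(assignment$set)[c("cal", "val", "test")]),
              class = "pony_split")
  })
}

#' @export
print.pony_split <- function(x, ...) {
  cat("Pony-level split:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build a run configuration
#'
#' Nested configuration for [run_full()]. Defaults reproduce the study
#' conditions (7 repair + 3 control ponies, 2 joints, 12 locations, 4
#' unreachable, paper-like effect size) with a selection budget sized
#' for a single-workstation run.
#'
#' @param parameters Reference parameters to model (subset of
#'   [reference_parameters()]).
#' @param variants Model variants to fit (`"Model1"`, `"Model2"`,
#'   `"Model3"`).
#' @param design A [study_design()].
#' @param effect An [effect_config()].
#' @param fractions Pony-level split fractions.
#' @param stride,budget,patience Forward-selection controls.
#' @param search_hidden,final_hidden Hidden widths for candidate search
#'   and final refit.
#' @param search_epochs,final_epochs Epoch caps.
#' @param seed Global seed.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(parameters = reference_parameters(),
                       variants = c("Model1", "Model2", "Model3"),
                       design = study_design(),
                       effect = effect_config(),
                       fractions = c(0.6, 0.3, 0.1),
                       stride = 8L, budget = 10L, patience = 3L,
                       search_hidden = 2L, final_hidden = 1:4,
                       search_epochs = 15L, final_epochs = 120L,
                       seed = 1L) {
  bad <- setdiff(parameters, reference_parameters())
  if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(variants, c("Model1", "Model2", "Model3"))
  if (length(bad)) stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  structure(list(parameters = parameters, variants = variants,
                 design = design, effect = effect, fractions = fractions,
                 stride = as.integer(stride), budget = as.integer(budget),
                 patience = as.integer(patience),
                 search_hidden = as.integer(search_hidden),
                 final_hidden = final_hidden,
                 search_epochs = as.integer(search_epochs),
                 final_epochs = as.integer(final_epochs),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields override [run_config()] defaults; design and effect
#' sub-maps override [study_design()] / [effect_config()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(study_design, raw$design %||% list())
  effect <- do.call(effect_config, raw$effect %||% list())
  args <- raw[setdiff(names(raw), c("design", "effect"))]
  do.call(run_config, c(args, list(design = design, effect = effect)))
}

# Fit one (parameter, variant) pair on preprocessed data and collect
# the evaluation sets.
fit_parameter_variant <- function(proc, refs, split, parameter,
                                  variant_name, config) {
  variant <- model_variant(variant_name)
  y_by_loc <- stats::setNames(refs[[parameter]], refs$loc_id)
  sel <- select_wavelengths(
    proc, y_by_loc, split, variant,
    stride = config$stride, budget = config$budget,
    patience = config$patience,
    search_control = ann_control(max_epochs = config$search_epochs,
                                 n_restarts = 1L),
    final_control = ann_control(max_epochs = config$final_epochs,
                                n_restarts = 2L),
    search_hidden = config$search_hidden,
    final_hidden = config$final_hidden,
    seed = derive_seed(config$seed,
                       match(parameter, reference_parameters()) * 10 +
                         match(variant_name, c("Model1", "Model2", "Model3"))))
  ds <- assemble_sets(proc, y_by_loc, split)
  idx <- sel$selected_idx
  pred <- function(X) predict(sel$fit, X[, idx, drop = FALSE])
  sets <- list(
    calval = list(y_true = c(ds$y_cal, ds$y_val),
                  y_pred = c(pred(ds$X_cal), pred(ds$X_val))),
    test = list(y_true = ds$y_test, y_pred = pred(ds$X_test)))
  if (identical(variant$criterion, "test_plus_arthro") &&
      !is.null(ds$X_arthro)) {
    agg <- aggregate_by_location(pred(ds$X_arthro), ds$arthro_loc)
    ok <- !is.na(agg$pred)
    sets$arthroscopic <- list(y_true = y_by_loc[agg$loc_id][ok],
                              y_pred = agg$pred[ok])
  }
  list(parameter = parameter, variant = variant_name,
       region = variant$region, n_variables = sel$n_variables,
       selection = sel, sets = sets)
}

#' Run the full analysis pipeline
#'
#' Simulates a study from the configured design, preprocesses both
#' modalities for each required (family, region) combination, splits
#' ponies into calibration/validation/test, runs forward wavelength
#' selection and Levenberg-Marquardt network training per (parameter,
#' variant), evaluates every set, and writes the report, QC table,
#' group summaries, per-model JSON fits and a machine-readable manifest
#' to `out_dir`. Arthroscopic spectra are never used for weight
#' fitting; they enter only Model 1's selection criterion and the final
#' arthroscopic evaluation.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   all file output.
#' @param study Optional pre-generated `"nirs_study"` (skips
#'   simulation).
#' @return Invisibly, a list with `report`, `group_summaries`, `qc`,
#'   `split`, `results`, `study`.
#' @export
run_full <- function(config = run_config(), out_dir = NULL, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- study %||% generate_study(config$design, config$effect,
                                     seed = config$seed)
  refs <- study$references
  if (nrow(refs) == 0) stopf("study is empty")
  split <- split_by_pony(refs, config$fractions,
                         seed = derive_seed(config$seed, 2))

  fams <- unique(parameter_family(config$parameters))
  regions <- unique(lapply(config$variants,
                           function(v) model_variant(v)$region))
  proc_cache <- list()
  proc_for <- function(fam, region) {
    key <- paste(fam, paste(region, collapse = "-"))
    if (is.null(proc_cache[[key]])) {
      proc_cache[[key]] <<- preprocess_study(study, fam, region)
    }
    proc_cache[[key]]
  }

  results <- list()
  for (param in config$parameters) {
    fam <- parameter_family(param)
    for (vn in config$variants) {
      region <- model_variant(vn)$region
      res <- fit_parameter_variant(proc_for(fam, region), refs, split,
                                   param, vn, config)
      results[[paste(param, vn, sep = ":")]] <- res
    }
  }

  ranges <- vapply(config$parameters,
                   function(p) diff(range(refs[[p]])), numeric(1))
  report <- build_report(results, as.list(ranges))

  gs <- do.call(rbind, lapply(config$parameters, function(p) {
    group_summary(refs[[p]], refs$group, refs$distance_class, p)
  }))
  qc <- proc_for(fams[1], regions[[1]])$qc

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    write.csv(gs, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
    if (!is.null(qc)) {
      write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    }
    fit_dir <- file.path(out_dir, "fits")
    dir.create(fit_dir, showWarnings = FALSE)
    for (nm in names(results)) {
      write_ann_json(results[[nm]]$selection$fit,
                     file.path(fit_dir, paste0(gsub(":", "_", nm), ".json")))
      jsonlite::write_json(
        list(selected_wavelengths_um =
               results[[nm]]$selection$selected_wavelengths,
             criterion_trajectory =
               results[[nm]]$selection$selection$trajectory),
        file.path(fit_dir, paste0(gsub(":", "_", nm), "_selection.json")),
        digits = NA, auto_unbox = TRUE)
    }
    manifest <- list(seed = config$seed,
                     parameters = config$parameters,
                     variants = config$variants,
                     fractions = config$fractions,
                     design = unclass(config$design),
                     effect = unclass(config$effect),
                     split = split$assignment,
                     package_version =
                       as.character(utils::packageVersion("arthronirs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(list(report = report, group_summaries = gs, qc = qc,
                 split = split, results = results, study = study))
}
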
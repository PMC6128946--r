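# Wide-CSV persistence for synthetic studies: one row per acquisition,
# metadata columns followed by one column per channel named by its
# wavelength in um (4 decimals), one file per spectrometer arm, plus a
# JSON manifest (grids, seed, design) and the reference table.

meta_columns <- function() {
  c("pony", "joint", "location", "group", "distance_class", "loc_id",
    "modality", "repeat_index", "contact_quality", "light_level")
}

#' Write a study to wide CSV + JSON manifest
#'
#' Writes `spectra_arm_a.csv` and `spectra_arm_b.csv` (metadata columns
#' then one intensity column per channel, named `wl_<um>` with 4
#' decimals), `references.csv` (one row per measured location), and
#' `manifest.json` (wavelength grids, seed, design, effect settings).
#'
#' @param study A `"nirs_study"`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in c("arm_a", "arm_b")) {
    M <- study[[arm]]
    colnames(M) <- sprintf("wl_%.4f", study$wavelengths[[arm]])
    write.csv(cbind(study$meta[, meta_columns()], M),
              file.path(dir, sprintf("spectra_%s.csv", arm)),
              row.names = FALSE)
  }
  write.csv(study$references, file.path(dir, "references.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed,
         design = unclass(study$design),
         effect = unclass(study$effect),
         arm_a_wavelengths = study$wavelengths$arm_a,
         arm_b_wavelengths = study$wavelengths$arm_b),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study written by [write_study_csv()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return A `"nirs_study"`.
#' @export
read_study_csv <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  read_arm <- function(arm) {
    df <- read.csv(file.path(dir, sprintf("spectra_%s.csv", arm)),
                   check.names = FALSE)
    wl_cols <- grep("^wl_", names(df))
    list(meta = df[, -wl_cols, drop = FALSE],
         M = as.matrix(df[, wl_cols, drop = FALSE]))
  }
  a <- read_arm("arm_a"); b <- read_arm("arm_b")
  design <- do.call(study_design,
                    man$design[setdiff(names(man$design), character(0))])
  effect <- do.call(effect_config, man$effect)
  A <- unname(a$M); B <- unname(b$M)
  structure(list(meta = a$meta, arm_a = A, arm_b = B,
                 wavelengths = list(arm_a = man$arm_a_wavelengths,
                                    arm_b = man$arm_b_wavelengths),
                 references = read.csv(file.path(dir, "references.csv")),
                 design = design, effect = effect,
                 seed = as.integer(man$seed)),
            class = "nirs_study")
}
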
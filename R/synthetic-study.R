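# Synthetic pony cartilage-repair study: design hierarchy, latent tissue
# states, reference tissue properties, and two-arm NIR spectra with
# arthroscopic acquisition artefacts.

# Fixed spectrometer grids (micrometres): a silicon-detector arm covering
# 0.35-1.1 um at 0.6 nm and an InGaAs arm covering 1.0-2.5 um at 6.4 nm.
arm_a_grid <- function() seq(0.35, 1.10, by = 0.0006)
arm_b_grid <- function() seq(1.00, 2.50, by = 0.0064)

# Population means for the control group (healthy joints): cartilage
# equilibrium/dynamic moduli, subchondral plate and trabecular bone
# structure, plus cartilage thickness used by the indentation protocol.
control_property_means <- function() {
  c(E_eq = 579, E_dyn = 7.25, plate_BV = 98.4, plate_BMD = 1.00,
    plate_thickness = 174, trab_BV = 30.5, trab_BMD = 0.247,
    trab_thickness = 169, SMI = 0.367, cartilage_thickness = 1000)
}

#' Define a study design
#'
#' Describes the hierarchical design of a cartilage-repair NIRS study:
#' repair and healthy control ponies, joints per pony, measurement
#' locations per joint (each assigned a distance class 1-4, increasing
#' distance from the repair site), surgically created lesions, and a
#' number of locations that are arthroscopically unreachable (excluded
#' from both modalities, as in the emulated study).
#'
#' @param n_repair_ponies,n_control_ponies Number of ponies per group.
#' @param joints_per_pony Joints measured per pony.
#' @param locations_per_joint Measurement locations per joint.
#' @param lesions_per_joint Chondral lesions created per repair joint.
#' @param n_unreachable Locations (within repair ponies) that cannot be
#'   reached arthroscopically; dropped from the measured set.
#' @param distance_class Integer vector of length `locations_per_joint`
#'   mapping location index to distance class 1-4.
#' @return An object of class `"nirs_design"`.
#' @examples
#' d <- study_design()
#' d$n_repair_ponies
#' @export
study_design <- function(n_repair_ponies = 7, n_control_ponies = 3,
                         joints_per_pony = 2, locations_per_joint = 12,
                         lesions_per_joint = 2, n_unreachable = 4,
                         distance_class = NULL) {
  counts <- c(n_repair_ponies, n_control_ponies, joints_per_pony,
              locations_per_joint, lesions_per_joint)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("invalid design: counts must be non-negative integers")
  }
  if (joints_per_pony < 1 || locations_per_joint < 1) {
    stopf("invalid design: joints_per_pony and locations_per_joint must be >= 1")
  }
  if (is.null(distance_class)) {
    distance_class <- rep_len(1:4, locations_per_joint)
  }
  if (length(distance_class) != locations_per_joint ||
      !all(distance_class %in% 1:4)) {
    stopf("distance_class must map every location to a class in 1..4")
  }
  max_unreach <- n_repair_ponies * joints_per_pony * locations_per_joint
  if (n_unreachable < 0 || n_unreachable > max_unreach) {
    stopf("n_unreachable must lie in [0, %d]", max_unreach)
  }
  structure(
    list(n_repair_ponies = as.integer(n_repair_ponies),
         n_control_ponies = as.integer(n_control_ponies),
         joints_per_pony = as.integer(joints_per_pony),
         locations_per_joint = as.integer(locations_per_joint),
         lesions_per_joint = as.integer(lesions_per_joint),
         n_unreachable = as.integer(n_unreachable),
         distance_class = as.integer(distance_class)),
    class = "nirs_design")
}

#' @export
print.nirs_design <- function(x, ...) {
  n_loc <- (x$n_repair_ponies + x$n_control_ponies) *
    x$joints_per_pony * x$locations_per_joint - x$n_unreachable
  cat("NIRS study design\n")
  cat(sprintf("  ponies: %d repair + %d control; %d joints each; %d locations/joint\n",
              x$n_repair_ponies, x$n_control_ponies, x$joints_per_pony,
              x$locations_per_joint))
  cat(sprintf("  lesions: %d; unreachable locations: %d; measured locations: %d\n",
              design_lesion_count(x), x$n_unreachable, n_loc))
  invisible(x)
}

#' Number of surgically created lesions implied by a design
#'
#' @param design A [study_design()] object.
#' @return Integer lesion count (repair ponies x joints x lesions per joint).
#' @export
design_lesion_count <- function(design) {
  design$n_repair_ponies * design$joints_per_pony * design$lesions_per_joint
}

#' Configure group-effect sizes and acquisition artefacts
#'
#' Controls how strongly tissue adjacent to repair sites is degraded
#' relative to control tissue, and the arthroscopic acquisition artefact
#' model. The degradation acts on latent tissue constituents (more
#' water, less proteoglycan/collagen/mineral) with a linear decay over
#' distance classes 1-4 so that tissue closest to the lesion is most
#' affected. `effect_size = 1` is the default "paper-like" degradation;
#' `effect_size = 0` makes repair and control exchangeable.
#'
#' @param effect_size Overall multiplier on the latent degradation.
#' @param class_decay Length-4 weight per distance class (class 1 first).
#' @param water,proteoglycan,collagen,mineral,scattering Latent shifts at
#'   class 1 for `effect_size = 1`.
#' @param contact_mode,contact_conc Mode and concentration of the Beta
#'   distribution of per-repeat arthroscopic probe contact quality
#'   (1 = perfect contact; in vitro acquisitions use 1).
#' @param light_base Arthroscope-light level for ordinary arthroscopic
#'   acquisitions (adds a broad bump confined to 0.42-0.75 um).
#' @param light_contaminated Light level at heavily contaminated
#'   locations; `n_light_contaminated` locations receive it.
#' @param n_light_contaminated Count of heavily light-contaminated
#'   arthroscopic locations per study.
#' @param noise_sd_invitro,noise_sd_arthro Additive intensity noise SD.
#' @return A list of class `"nirs_effect"`.
#' @export
effect_config <- function(effect_size = 1,
                          class_decay = c(1, 0.75, 0.5, 0.25),
                          water = 0.05, proteoglycan = -0.25,
                          collagen = -0.15, mineral = -0.12,
                          scattering = 0.05,
                          contact_mode = 0.85, contact_conc = 8,
                          light_base = 0.03, light_contaminated = 0.6,
                          n_light_contaminated = 4,
                          noise_sd_invitro = 0.004,
                          noise_sd_arthro = 0.008) {
  stopifnot(length(class_decay) == 4, effect_size >= 0,
            contact_mode > 0, contact_mode <= 1)
  structure(
    list(effect_size = effect_size, class_decay = class_decay,
         water = water, proteoglycan = proteoglycan, collagen = collagen,
         mineral = mineral, scattering = scattering,
         contact_mode = contact_mode, contact_conc = contact_conc,
         light_base = light_base, light_contaminated = light_contaminated,
         n_light_contaminated = as.integer(n_light_contaminated),
         noise_sd_invitro = noise_sd_invitro,
         noise_sd_arthro = noise_sd_arthro),
    class = "nirs_effect")
}

# Draw latent tissue states for n locations of a given group/class.
# Control latents are centred at (water 0.72, collagen 1, PG 1, mineral 1,
# scattering 0.5); repair latents are shifted by effect * class_decay.
draw_latent_states <- function(n, group, distance_class, effect) {
  s <- if (group == "repair") {
    effect$effect_size * effect$class_decay[distance_class]
  } else {
    rep(0, length(distance_class))
  }
  if (length(s) == 1) s <- rep(s, n)
  data.frame(
    water_fraction   = pmin(0.85, pmax(0.60, rnorm(n, 0.72, 0.03) + effect$water * s)),
    collagen_density = pmax(0.2, rnorm(n, 1, 0.10) + effect$collagen * s),
    proteoglycan_density = pmax(0.2, rnorm(n, 1, 0.12) + effect$proteoglycan * s),
    mineral_density  = pmax(0.2, rnorm(n, 1, 0.08) + effect$mineral * s),
    scattering_slope = pmax(0.1, rnorm(n, 0.5, 0.05) + effect$scattering * s))
}

# Deterministic monotone map latent -> reference properties, plus small
# measurement noise. Each property is monotone in each latent it uses:
#   E_eq, E_dyn   : + proteoglycan, + collagen, - water
#   plate/trab BV, BMD, thickness : + mineral (thickness also + collagen)
#   SMI           : - mineral (degraded bone becomes rod-like)
#   cartilage thickness : + collagen
latent_to_properties <- function(lat) {
  n <- nrow(lat)
  m <- control_property_means()
  dw <- lat$water_fraction - 0.72
  dc <- lat$collagen_density - 1
  dp <- lat$proteoglycan_density - 1
  dm <- lat$mineral_density - 1
  data.frame(
    E_eq = softplus(m[["E_eq"]] * (1 + 0.45 * dp + 0.30 * dc - 3.0 * dw) +
                      rnorm(n, 0, 17), 25),
    E_dyn = softplus(m[["E_dyn"]] * (1 + 0.40 * dp + 0.35 * dc - 2.5 * dw) +
                       rnorm(n, 0, 0.20), 0.5),
    plate_BV = 100 - 1.6 * exp(-2.2 * dm + rnorm(n, 0, 0.05)),
    plate_BMD = softplus(m[["plate_BMD"]] * (1 + 0.5 * dm) + rnorm(n, 0, 0.02), 0.05),
    plate_thickness = softplus(m[["plate_thickness"]] * (1 + 0.30 * dm + 0.10 * dc) +
                                 rnorm(n, 0, 6), 5),
    trab_BV = pmin(100, softplus(m[["trab_BV"]] * (1 + 0.35 * dm) + rnorm(n, 0, 1), 2)),
    trab_BMD = softplus(m[["trab_BMD"]] * (1 + 0.5 * dm) + rnorm(n, 0, 0.008), 0.01),
    trab_thickness = softplus(m[["trab_thickness"]] * (1 + 0.30 * dm) +
                                rnorm(n, 0, 5), 5),
    SMI = m[["SMI"]] - 1.8 * dm + rnorm(n, 0, 0.05),
    cartilage_thickness = softplus(m[["cartilage_thickness"]] * (1 + 0.20 * dc) +
                                     rnorm(n, 0, 30), 20))
}

#' Names of the nine modelled reference parameters
#'
#' Cartilage equilibrium and dynamic moduli, subchondral plate bone
#' volume fraction / mineral density / thickness, and trabecular bone
#' volume fraction / mineral density / thickness / structure model index.
#' (Cartilage thickness is carried as a reference value but not modelled.)
#' @return Character vector of length 9.
#' @export
reference_parameters <- function() {
  c("E_eq", "E_dyn", "plate_BV", "plate_BMD", "plate_thickness",
    "trab_BV", "trab_BMD", "trab_thickness", "SMI")
}

#' Simulate reference tissue properties for one group and distance class
#'
#' Draws latent tissue states for `n` locations and maps them through
#' the documented monotone latent-to-property model. Control draws are
#' centred on the healthy-population means (e.g. 579 kPa equilibrium
#' modulus); repair draws are degraded by `effect`, with the shift
#' decaying linearly over distance classes.
#'
#' @param group `"repair"` or `"control"`.
#' @param distance_class Integer in 1..4.
#' @param n Number of locations to draw.
#' @param effect An [effect_config()].
#' @param seed Optional integer seed.
#' @return A data frame with one row per draw and the 10 property columns.
#' @examples
#' p <- simulate_reference_properties("control", 1, n = 5, seed = 1)
#' p$E_eq
#' @export
simulate_reference_properties <- function(group, distance_class, n = 1,
                                          effect = effect_config(),
                                          seed = NULL) {
  group <- match.arg(group, c("repair", "control"))
  if (!all(distance_class %in% 1:4)) stopf("distance_class must be in 1..4")
  with_seed(seed, {
    lat <- draw_latent_states(n, group, rep_len(distance_class, n), effect)
    latent_to_properties(lat)
  })
}

#' Describe an acquisition context
#'
#' @param modality `"arthroscopic"` or `"in_vitro"`.
#' @param contact_quality Probe contact quality in (0, 1]; 1 = perfect.
#' @param arthroscope_light_level Arthroscope-light contamination level
#'   (must be 0 in vitro).
#' @param n_repeats Repeat acquisitions at the location (defaults: 15
#'   arthroscopic, 3 in vitro).
#' @param noise_sd Additive intensity noise SD.
#' @return A list of class `"acquisition_context"`.
#' @export
acquisition_context <- function(modality = c("arthroscopic", "in_vitro"),
                                contact_quality = 1,
                                arthroscope_light_level = 0,
                                n_repeats = NULL, noise_sd = 0.004) {
  modality <- match.arg(modality)
  if (modality == "in_vitro" && arthroscope_light_level != 0) {
    stopf("in_vitro acquisitions have no arthroscope light")
  }
  if (arthroscope_light_level < 0) stopf("light level must be >= 0")
  n_repeats <- n_repeats %||% if (modality == "arthroscopic") 15L else 3L
  structure(list(modality = modality,
                 contact_quality = contact_quality,
                 arthroscope_light_level = arthroscope_light_level,
                 n_repeats = as.integer(n_repeats), noise_sd = noise_sd),
            class = "acquisition_context")
}

# Deterministic (noise-free) forward spectral model for one latent state.
# Returns list(arm_a, arm_b) of clean intensities on the fixed grids.
# Reflectance-style construction: smooth scattering baseline minus
# Gaussian absorption bands. Water OH bands at 0.97/1.45/1.93 um, CH
# bands at 0.90/1.18/1.73 um, NH bands at 1.00/1.50 um; band depths are
# attenuated by imperfect probe contact.
spectral_forward <- function(state, contact_quality = 1,
                             light_level = 0) {
  cq <- min(1, max(0, contact_quality))
  gauss <- function(l, c, w) exp(-0.5 * ((l - c) / w)^2)
  bands <- function(l) {
    w <- state$water_fraction * cq
    co <- state$collagen_density * cq
    pg <- state$proteoglycan_density * cq
    0.10 * w * gauss(l, 0.97, 0.030) +
      0.28 * w * gauss(l, 1.45, 0.045) +
      0.55 * w * gauss(l, 1.93, 0.060) +
      0.03 * co * gauss(l, 0.90, 0.020) +
      0.05 * co * gauss(l, 1.18, 0.030) +
      0.08 * co * gauss(l, 1.73, 0.040) +
      0.04 * pg * gauss(l, 1.00, 0.030) +
      0.06 * pg * gauss(l, 1.50, 0.040)
  }
  base <- function(l) {
    s_eff <- 0.35 * (state$scattering_slope + 0.30 * (state$mineral_density - 1))
    1.1 * exp(-s_eff * (l - 0.35))
  }
  # Arthroscope light: smooth bump with support exactly [0.42, 0.75] um.
  bump <- function(l) {
    inside <- l >= 0.42 & l <= 0.75
    out <- numeric(length(l))
    out[inside] <- light_level * sin(pi * (l[inside] - 0.42) / 0.33)^2
    out
  }
  la <- arm_a_grid(); lb <- arm_b_grid()
  list(arm_a = base(la) - bands(la) + bump(la),
       arm_b = base(lb) - bands(lb) + bump(lb))
}

# Detector dynamic range and the saturation model for channels >= 1.9 um:
# clipped at 95% of full scale with 5x inflated noise (the region is
# discarded during preprocessing; only its unusability matters).
detector_full_scale <- function() 1.2
saturation_onset <- function() 1.90

#' Simulate a raw two-arm NIR spectrum
#'
#' Forward model: smooth scattering baseline minus Gaussian absorption
#' bands (water OH at 0.97/1.45/1.93 um scaled by water fraction and
#' probe contact; CH at 0.90/1.18/1.73 um; NH at 1.00/1.50 um; baseline
#' slope tied to mineral density) plus additive noise. Channels at or
#' above 1.9 um are driven to detector saturation. Arthroscope light
#' adds a broad bump confined to 0.42-0.75 um. Contact quality below 1
#' attenuates band depths and inflates noise.
#'
#' @param state List/row with `water_fraction`, `collagen_density`,
#'   `proteoglycan_density`, `mineral_density`, `scattering_slope`.
#'   Out-of-range values are clamped with a warning.
#' @param context An [acquisition_context()].
#' @param seed Optional integer seed (noise reproducibility).
#' @return A list of class `"raw_spectrum"` with `arm_a_wavelengths`,
#'   `arm_a_intensity`, `arm_b_wavelengths`, `arm_b_intensity`, `metadata`.
#' @examples
#' st <- list(water_fraction = 0.72, collagen_density = 1,
#'            proteoglycan_density = 1, mineral_density = 1,
#'            scattering_slope = 0.5)
#' sp <- simulate_spectrum(st, acquisition_context("in_vitro"), seed = 1)
#' range(sp$arm_a_intensity)
#' @export
simulate_spectrum <- function(state, context = acquisition_context(),
                              seed = NULL) {
  state <- as.list(state)
  if (state$water_fraction < 0.6 || state$water_fraction > 0.85) {
    warning("water_fraction clamped to [0.6, 0.85]")
    state$water_fraction <- min(0.85, max(0.6, state$water_fraction))
  }
  with_seed(seed, {
    clean <- spectral_forward(state, context$contact_quality,
                              context$arthroscope_light_level)
    raw_spectrum_from_clean(clean, context)
  })
}

# Add noise + saturation to a clean forward spectrum; uses current RNG.
raw_spectrum_from_clean <- function(clean, context, metadata = list()) {
  cq <- min(1, max(1e-3, context$contact_quality))
  noise_sd <- context$noise_sd * (2 - cq)
  la <- arm_a_grid(); lb <- arm_b_grid()
  ia <- clean$arm_a + rnorm(length(la), 0, noise_sd)
  ib <- clean$arm_b + rnorm(length(lb), 0, noise_sd)
  sat <- lb >= saturation_onset()
  ib[sat] <- 0.95 * detector_full_scale() +
    rnorm(sum(sat), 0, 5 * max(noise_sd, 1e-6))
  structure(list(arm_a_wavelengths = la, arm_a_intensity = pmax(ia, 0),
                 arm_b_wavelengths = lb, arm_b_intensity = pmax(ib, 0),
                 metadata = metadata),
            class = "raw_spectrum")
}

#' Generate a full synthetic study
#'
#' Builds the complete hierarchy (ponies, joints, locations), drops the
#' arthroscopically unreachable locations from both modalities, draws
#' one latent tissue state and one reference-property record per
#' measured location, and simulates all repeat acquisitions: in vitro
#' repeats at perfect contact with no arthroscope light, and (for repair
#' ponies) arthroscopic repeats with Beta-distributed per-repeat contact
#' quality and arthroscope-light contamination (a configurable number of
#' locations being heavily contaminated). The whole dataset is a pure
#' function of `(design, effect, seed)`.
#'
#' @param design A [study_design()].
#' @param effect An [effect_config()].
#' @param seed Integer seed.
#' @return An object of class `"nirs_study"`: `meta` (one row per
#'   acquisition), intensity matrices `arm_a`/`arm_b` (rows matching
#'   `meta`), `wavelengths`, `references` (one row per measured
#'   location), `design`, `effect`, `seed`.
#' @examples
#' st <- generate_study(study_design(n_repair_ponies = 1,
#'                                   n_control_ponies = 1,
#'                                   n_unreachable = 0), seed = 1)
#' nrow(st$references)
#' @export
generate_study <- function(design = study_design(),
                           effect = effect_config(), seed = 1L) {
  stopifnot(inherits(design, "nirs_design"))
  with_seed(seed, {
    ponies <- c(if (design$n_repair_ponies > 0)
                  sprintf("R%02d", seq_len(design$n_repair_ponies)),
                if (design$n_control_ponies > 0)
                  sprintf("C%02d", seq_len(design$n_control_ponies)))
    if (is.null(ponies)) {
      return(structure(list(meta = data.frame(), arm_a = NULL, arm_b = NULL,
                            wavelengths = list(arm_a = arm_a_grid(),
                                               arm_b = arm_b_grid()),
                            references = data.frame(), design = design,
                            effect = effect, seed = seed),
                       class = "nirs_study"))
    }
    group <- ifelse(grepl("^R", ponies), "repair", "control")
    loc <- expand.grid(location = seq_len(design$locations_per_joint),
                       joint = seq_len(design$joints_per_pony),
                       pony = ponies, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    loc <- loc[, c("pony", "joint", "location")]
    loc$group <- group[match(loc$pony, ponies)]
    loc$distance_class <- design$distance_class[loc$location]
    loc$loc_id <- sprintf("%s_j%d_l%02d", loc$pony, loc$joint, loc$location)

    # Unreachable locations: drawn among repair-pony locations, dropped
    # from both modalities.
    if (design$n_unreachable > 0) {
      repair_rows <- which(loc$group == "repair")
      drop <- sample(repair_rows, design$n_unreachable)
      loc <- loc[-drop, , drop = FALSE]
    }
    rownames(loc) <- NULL

    lat <- draw_latent_states(nrow(loc), "control", loc$distance_class,
                              effect)
    # redo with per-row group (draw_latent_states takes one group label)
    rep_rows <- loc$group == "repair"
    s <- ifelse(rep_rows,
                effect$effect_size * effect$class_decay[loc$distance_class], 0)
    lat$water_fraction <- pmin(0.85, pmax(0.60, lat$water_fraction + effect$water * s))
    lat$collagen_density <- pmax(0.2, lat$collagen_density + effect$collagen * s)
    lat$proteoglycan_density <- pmax(0.2, lat$proteoglycan_density + effect$proteoglycan * s)
    lat$mineral_density <- pmax(0.2, lat$mineral_density + effect$mineral * s)
    lat$scattering_slope <- pmax(0.1, lat$scattering_slope + effect$scattering * s)

    refs <- cbind(loc, latent_to_properties(lat))

    # Heavily light-contaminated arthroscopic locations (repair ponies).
    arthro_loc <- which(rep_rows)
    contaminated <- if (length(arthro_loc) > 0 && effect$n_light_contaminated > 0) {
      sample(arthro_loc, min(effect$n_light_contaminated, length(arthro_loc)))
    } else integer(0)

    n_iv <- 3L
    n_ar <- 15L
    n_acq <- nrow(loc) * n_iv + length(arthro_loc) * n_ar
    la <- arm_a_grid(); lb <- arm_b_grid()
    A <- matrix(NA_real_, n_acq, length(la))
    B <- matrix(NA_real_, n_acq, length(lb))
    meta <- vector("list", nrow(loc) + length(arthro_loc))
    # Beta(mode, concentration) contact-quality parameters
    sh1 <- 1 + effect$contact_mode * effect$contact_conc
    sh2 <- 1 + (1 - effect$contact_mode) * effect$contact_conc

    row <- 0L; blk <- 0L
    for (i in seq_len(nrow(loc))) {
      st <- lat[i, ]
      # in vitro: 3 repeats, perfect contact, no arthroscope light
      clean <- spectral_forward(st, 1, 0)
      ctx <- acquisition_context("in_vitro", 1, 0, n_iv,
                                 effect$noise_sd_invitro)
      for (r in seq_len(n_iv)) {
        sp <- raw_spectrum_from_clean(clean, ctx)
        row <- row + 1L
        A[row, ] <- sp$arm_a_intensity; B[row, ] <- sp$arm_b_intensity
      }
      blk <- blk + 1L
      meta[[blk]] <- data.frame(loc[i, , drop = FALSE],
                                modality = "in_vitro",
                                repeat_index = seq_len(n_iv),
                                contact_quality = 1,
                                light_level = 0, row.names = NULL)
      if (rep_rows[i]) {
        light <- if (i %in% contaminated) effect$light_contaminated else
          effect$light_base
        cqs <- rbeta(n_ar, sh1, sh2)
        for (r in seq_len(n_ar)) {
          cl <- spectral_forward(st, cqs[r], light)
          ctx <- acquisition_context("arthroscopic", cqs[r], light, 1,
                                     effect$noise_sd_arthro)
          sp <- raw_spectrum_from_clean(cl, ctx)
          row <- row + 1L
          A[row, ] <- sp$arm_a_intensity; B[row, ] <- sp$arm_b_intensity
        }
        blk <- blk + 1L
        meta[[blk]] <- data.frame(loc[i, , drop = FALSE],
                                  modality = "arthroscopic",
                                  repeat_index = seq_len(n_ar),
                                  contact_quality = cqs,
                                  light_level = light, row.names = NULL)
      }
    }
    meta <- do.call(rbind, meta)
    rownames(meta) <- NULL
    structure(list(meta = meta, arm_a = A, arm_b = B,
                   wavelengths = list(arm_a = la, arm_b = lb),
                   references = refs, design = design, effect = effect,
                   seed = as.integer(seed)),
              class = "nirs_study")
  })
}

#' @export
print.nirs_study <- function(x, ...) {
  cat("Synthetic NIRS study\n")
  if (nrow(x$references) == 0) {
    cat("  (empty)\n"); return(invisible(x))
  }
  cat(sprintf("  measured locations: %d (%d in vitro, %d arthroscopic)\n",
              nrow(x$references),
              length(unique(x$meta$loc_id[x$meta$modality == "in_vitro"])),
              length(unique(x$meta$loc_id[x$meta$modality == "arthroscopic"]))))
  cat(sprintf("  acquisitions: %d; seed: %d\n", nrow(x$meta), x$seed))
  invisible(x)
}
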
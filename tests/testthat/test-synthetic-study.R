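# Synthetic study generator: design arithmetic, determinism, latent ->
# property model, and the spectral forward model.

test_that("study design validates its inputs and counts locations", {
  d <- study_design()
  expect_s3_class(d, "nirs_design")
  expect_equal(design_lesion_count(d), 28)
  expect_error(study_design(n_repair_ponies = -1), "invalid design")
  expect_error(study_design(distance_class = rep(5, 12)), "class in 1..4")
})

test_that("default design yields the expected measured-location counts", {
  st <- default_study()
  expect_equal(nrow(st$references), 236)
  iv <- st$meta$modality == "in_vitro"
  expect_equal(length(unique(st$meta$loc_id[iv])), 236)
  expect_equal(length(unique(st$meta$loc_id[!iv])), 164)
  # repeats per location: 3 in vitro, 15 arthroscopic
  expect_true(all(table(st$meta$loc_id[iv]) == 3))
  expect_true(all(table(st$meta$loc_id[!iv]) == 15))
})

test_that("generation is a pure function of design, effect and seed", {
  d <- study_design(n_repair_ponies = 2, n_control_ponies = 1,
                    joints_per_pony = 1, locations_per_joint = 4,
                    n_unreachable = 1)
  a <- generate_study(d, seed = 42)
  b <- generate_study(d, seed = 42)
  expect_identical(a$arm_a, b$arm_a)
  expect_identical(a$arm_b, b$arm_b)
  expect_identical(a$references, b$references)
  c3 <- generate_study(d, seed = 43)
  expect_false(identical(a$arm_a, c3$arm_a))
})

test_that("zero ponies produce an empty dataset", {
  st <- generate_study(study_design(n_repair_ponies = 0,
                                    n_control_ponies = 0,
                                    n_unreachable = 0), seed = 1)
  expect_equal(nrow(st$references), 0)
})

test_that("generated spectra satisfy the raw-spectrum invariants", {
  st <- small_study()
  expect_true(all(diff(st$wavelengths$arm_a) > 0))
  expect_true(all(diff(st$wavelengths$arm_b) > 0))
  expect_true(all(is.finite(st$arm_a)), all(st$arm_a >= 0))
  expect_true(all(is.finite(st$arm_b)), all(st$arm_b >= 0))
})

test_that("control reference draws are centred on the population means", {
  p <- simulate_reference_properties("control", 2, n = 1e4, seed = 1)
  se <- sd(p$E_eq) / sqrt(nrow(p))
  expect_lt(abs(mean(p$E_eq) - 579), 2 * se)
  # remaining properties within 1% of their nominal centres
  expect_equal(mean(p$plate_BV), 98.4, tolerance = 0.01)
  expect_equal(mean(p$trab_BV), 30.5, tolerance = 0.01)
  expect_equal(mean(p$plate_BMD), 1.00, tolerance = 0.01)
  expect_true(all(p$plate_BV <= 100), all(p$trab_BV <= 100))
  expect_true(all(p$E_eq > 0), all(p$E_dyn > 0))
})

test_that("zero effect size makes repair and control exchangeable", {
  a <- simulate_reference_properties("repair", 1, n = 50,
                                     effect = effect_config(effect_size = 0),
                                     seed = 9)
  b <- simulate_reference_properties("control", 1, n = 50,
                                     effect = effect_config(effect_size = 0),
                                     seed = 9)
  expect_identical(a, b)
})

test_that("repair degradation decays with distance class", {
  e1 <- simulate_reference_properties("repair", 1, n = 1e4, seed = 3)$E_eq
  e4 <- simulate_reference_properties("repair", 4, n = 1e4, seed = 4)$E_eq
  ctl <- simulate_reference_properties("control", 1, n = 1e4, seed = 5)$E_eq
  shift1 <- abs(mean(e1) - mean(ctl))
  shift4 <- abs(mean(e4) - mean(ctl))
  expect_gt(shift1, shift4)
})

test_that("water-band depth at 1.45 um is monotone in water fraction", {
  la <- default_study()$wavelengths$arm_b
  idx <- which.min(abs(la - 1.45))
  depths <- vapply(seq(0.62, 0.84, length.out = 5), function(w) {
    cl <- arthronirs:::spectral_forward(center_state(w), 1, 0)
    base <- arthronirs:::spectral_forward(
      modifyList(center_state(w), list(water_fraction = 0.6)), 1, 0)
    base$arm_b[idx] - cl$arm_b[idx]
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("spectra differing only in water differ only inside water bands", {
  a <- arthronirs:::spectral_forward(center_state(0.65), 1, 0)
  b <- arthronirs:::spectral_forward(center_state(0.80), 1, 0)
  la <- arthronirs:::arm_a_grid()
  lb <- arthronirs:::arm_b_grid()
  water_support <- function(l) {
    (abs(l - 0.97) <= 3 * 0.030) | (abs(l - 1.45) <= 3 * 0.045) |
      (abs(l - 1.93) <= 3 * 0.060)
  }
  outside_a <- !water_support(la)
  outside_b <- !water_support(lb)
  # beyond 3 sigma only far Gaussian tails remain (< 2% of the in-band
  # effect); inside the bands the water difference is order 10^-2
  max_in <- max(abs(a$arm_b[!outside_b] - b$arm_b[!outside_b]))
  expect_gt(max_in, 0.01)
  expect_lt(max(abs(a$arm_a[outside_a] - b$arm_a[outside_a])), 0.02 * max_in)
  expect_lt(max(abs(a$arm_b[outside_b] - b$arm_b[outside_b])), 0.02 * max_in)
})

test_that("arthroscope light is confined to 0.42-0.75 um", {
  st <- center_state()
  ctx0 <- acquisition_context("arthroscopic", 1, 0, noise_sd = 0)
  ctx1 <- acquisition_context("arthroscopic", 1, 0.5, noise_sd = 0)
  s0 <- simulate_spectrum(st, ctx0, seed = 2)
  s1 <- simulate_spectrum(st, ctx1, seed = 2)
  la <- s0$arm_a_wavelengths
  vis <- la >= 0.42 & la <= 0.75
  expect_equal(s0$arm_a_intensity[!vis], s1$arm_a_intensity[!vis])
  expect_gt(mean(s1$arm_a_intensity[vis] - s0$arm_a_intensity[vis]), 0.1)
})

test_that("out-of-range latent water is clamped with a warning", {
  expect_warning(
    simulate_spectrum(center_state(0.95), acquisition_context("in_vitro"),
                      seed = 1),
    "clamped")
})

test_that("in vitro contexts reject arthroscope light", {
  expect_error(acquisition_context("in_vitro", arthroscope_light_level = 1),
               "no arthroscope light")
})

test_that("channels beyond 1.9 um are saturated and unusable", {
  sp <- simulate_spectrum(center_state(),
                          acquisition_context("in_vitro", noise_sd = 0.004),
                          seed = 6)
  sat <- sp$arm_b_wavelengths >= 1.90
  expect_gt(min(sp$arm_b_intensity[sat]), 1.0)  # pinned near full scale
})

test_that("study CSV round-trips through write/read", {
  st <- small_study()
  dir <- withr::local_tempdir()
  write_study_csv(st, dir)
  back <- read_study_csv(dir)
  expect_equal(back$arm_a, st$arm_a, tolerance = 1e-12)
  expect_equal(back$references$E_eq, st$references$E_eq, tolerance = 1e-12)
  expect_equal(back$meta$loc_id, st$meta$loc_id)
})
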
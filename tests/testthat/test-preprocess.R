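# Preprocessing: Savitzky-Golay smoothing, trimming/merging, contact
# area statistic, repeat retention, contamination flagging, CV.

test_that("SG smoothing preserves polynomials up to its order", {
  x <- seq(0, 1, length.out = 80)
  expect_equal(sg_smooth(rep(3, 80), window = 13), rep(3, 80))
  cubic <- 1 - 2 * x + 0.5 * x^2 + 4 * x^3
  expect_equal(sg_smooth(cubic, window = 25), cubic, tolerance = 1e-9)
})

test_that("interior SG values match the per-window polyfit oracle", {
  set.seed(1)
  y <- cumsum(rnorm(60))
  sm <- sg_smooth(y, window = 13)
  or <- sg_polyfit_oracle(y, 13)
  keep <- !is.na(or)
  expect_equal(sm[keep], or[keep], tolerance = 1e-8)
})

test_that("SG parameters are validated", {
  y <- rnorm(30)
  expect_error(sg_smooth(y, window = 12), "odd")
  expect_error(sg_smooth(y, window = 3, order = 3), "exceed")
  expect_error(sg_smooth(y, window = 31), "length")
})

test_that("family variants use the documented smoothing windows", {
  st <- center_state()
  raw <- simulate_spectrum(st, acquisition_context("in_vitro"), seed = 1)
  pc <- preprocess_for("cartilage", raw)
  pb <- preprocess_for("bone", raw)
  expect_equal(unname(pc$windows), c(25L, 13L))
  expect_equal(unname(pb$windows), c(45L, 13L))
})

test_that("region trimming and arm merging obey their contracts", {
  raw <- simulate_spectrum(center_state(), acquisition_context("in_vitro"),
                           seed = 2)
  for (region in list(c(0.75, 1.90), c(0.40, 1.90))) {
    p <- preprocess_for("cartilage", raw, region)
    expect_gte(min(p$wavelengths), region[1])
    expect_lt(max(p$wavelengths), 1.90)
    # strictly increasing, single authoritative channel per wavelength
    expect_true(all(diff(p$wavelengths) > 0))
    # overlap region 1.0-1.1 um resolved to the arm-b channels only
    lb <- arthronirs:::arm_b_grid()
    expect_equal(sum(p$wavelengths >= 1.0 & p$wavelengths < 1.1),
                 sum(lb >= 1.0 & lb < 1.1))
  }
  expect_error(preprocess_for("cartilage", raw, c(0.2, 2.2)), "region")
})

test_that("region trimming is idempotent", {
  plan1 <- arthronirs:::merge_plan(c(0.75, 1.90))
  keep <- plan1$wavelengths >= 0.75 & plan1$wavelengths < 1.90
  expect_true(all(keep))  # trimming again changes nothing
})

test_that("contact area is zero for a linear spectrum and scales linearly", {
  la <- arthronirs:::arm_a_grid()
  linear <- 2 + 0.5 * la
  expect_equal(contact_area(linear, smoothed = FALSE), 0, tolerance = 1e-12)
  # triangular bump of height h and base W, endpoints on the line
  cr <- arthronirs:::contact_region_idx()
  mid <- (0.42 + 0.75) / 2
  W <- 0.2; h <- 0.1
  tri <- pmax(0, h * (1 - abs(la - mid) / (W / 2)))
  area <- contact_area(linear + tri, smoothed = FALSE)
  expect_equal(area, h * W / 2, tolerance = 1e-3)
  # doubling the deviation doubles the area
  expect_equal(contact_area(linear + 2 * tri, smoothed = FALSE), 2 * area,
               tolerance = 1e-9)
})

test_that("batch contact areas match the single-spectrum statistic", {
  st <- small_study()
  rows <- sample(nrow(st$arm_a), 5)
  batch <- arthronirs:::contact_area_matrix(st$arm_a[rows, , drop = FALSE])
  single <- vapply(rows, function(r) contact_area(st$arm_a[r, ]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-10)
})

test_that("best-spectra retention keeps the smallest areas with stable ties", {
  expect_equal(select_best_spectra(15:1), 15:8)
  expect_equal(select_best_spectra(rep(1, 15)), 1:8)
  expect_length(select_best_spectra(runif(15)), 8)
  expect_error(select_best_spectra(runif(5)), "at least 8")
  # permutation invariance of the retained set
  areas <- c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10, 11, 12, 13, 14, 15)
  perm <- sample(15)
  kept1 <- sort(areas[select_best_spectra(areas)])
  kept2 <- sort(areas[perm][select_best_spectra(areas[perm])])
  expect_equal(kept1, kept2)
})

test_that("mean contact area increases with arthroscope light level", {
  st <- center_state()
  levels <- c(0, 0.05, 0.2, 0.6)
  means <- vapply(levels, function(lv) {
    areas <- vapply(1:25, function(r) {
      sp <- simulate_spectrum(st, acquisition_context("arthroscopic",
                                                      contact_quality = 0.9,
                                                      arthroscope_light_level = lv,
                                                      noise_sd = 0.008),
                              seed = 100 + r)
      contact_area(sp)
    }, numeric(1))
    mean(areas)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("contamination flagging isolates high-light locations", {
  st <- small_study()  # one contaminated location by construction
  proc <- preprocess_study(st, "cartilage", c(0.75, 1.90))
  hi <- unique(st$meta$loc_id[st$meta$light_level > 0.1])
  expect_setequal(proc$qc$loc_id[proc$qc$flagged], hi)
  # degenerate threshold never flags
  expect_false(flag_contaminated_location(c(10, 20, 30), Inf))
})

test_that("coefficient of variation matches its two-point closed form", {
  raw <- simulate_spectrum(center_state(), acquisition_context("in_vitro"),
                           seed = 3)
  p1 <- preprocess_for("cartilage", raw)
  p2 <- p1
  expect_equal(coefficient_of_variation(p1, p2), 0)
  p2$intensity <- 1.02 * p1$intensity
  # population SD / mean of {x, 1.02x} = 0.01/1.01
  expect_equal(coefficient_of_variation(p1, p2), 100 * 0.01 / 1.01,
               tolerance = 1e-10)
  expect_error(coefficient_of_variation(p1, p2, region = c(2.0, 2.4)),
               "region")
})

test_that("preprocessed study matrices line up with their metadata", {
  st <- small_study()
  proc <- preprocess_study(st, "bone", c(0.40, 1.90))
  expect_equal(nrow(proc$X_invitro), nrow(st$references))
  expect_equal(proc$invitro_meta$loc_id,
               unique(st$meta$loc_id[st$meta$modality == "in_vitro"]))
  expect_equal(nrow(proc$X_arthro), 8 * nrow(proc$qc))
  expect_true(all(proc$wavelengths >= 0.40 & proc$wavelengths < 1.90))
})
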
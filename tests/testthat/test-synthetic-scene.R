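# The scene generator: endmember placement, the scatter/noise model,
# and cohort structure.

test_that("phenolic signature peaks sit in the CH-overtone windows", {
  wl <- seq(920, 1970, by = 10)
  for (s in 1:5) {
    basis <- generate_basis_spectra(wl, "SWIR", seed = s)
    sig <- basis$signature
    expect_true(all(sig >= 0))
    # global maximum in one window...
    peak_wl <- wl[which.max(sig)]
    expect_true((peak_wl >= 1110 && peak_wl <= 1130) ||
                  (peak_wl >= 1645 && peak_wl <= 1670))
    # ...and both planted centres inside their windows
    expect_gte(basis$signature_centres[1], 1110)
    expect_lte(basis$signature_centres[1], 1130)
    expect_gte(basis$signature_centres[2], 1645)
    expect_lte(basis$signature_centres[2], 1670)
    # compact support: negligible far from both windows
    expect_lt(sig[which.min(abs(wl - 1900))], 0.01 * max(sig))
  }
})

test_that("VIS/NIR signature peaks sit in the visible phenolic windows", {
  wl <- seq(400, 1000, by = 5)
  basis <- generate_basis_spectra(wl, "VISNIR", seed = 2)
  expect_gte(basis$signature_centres[1], 450)
  expect_lte(basis$signature_centres[1], 475)
  expect_gte(basis$signature_centres[2], 535)
  expect_lte(basis$signature_centres[2], 565)
  expect_true(all(basis$vegetation >= 0 & basis$vegetation <= 1))
  expect_true(all(basis$soil >= 0 & basis$soil <= 1))
})

test_that("basis generation is deterministic and validates its grid", {
  wl <- seq(920, 1970, by = 10)
  expect_identical(generate_basis_spectra(wl, "SWIR", seed = 4),
                   generate_basis_spectra(wl, "SWIR", seed = 4))
  expect_error(generate_basis_spectra(seq(400, 990, 5), "SWIR", seed = 1),
               class = "phenomap_error_invalid_grid")
  expect_error(generate_basis_spectra(rev(wl), "SWIR", seed = 1),
               class = "phenomap_error_invalid_grid")
})

test_that("calibration of a zero-noise scene recovers the latent reflectance", {
  scene <- noiseless_scene(concentration = 1.5, seed = 7)
  cal <- calibrate_reflectance(scene$cube, scene$refs)
  basis <- generate_basis_spectra(cal$wavelengths_nm, "SWIR", seed = 7L)
  expected_plant <- basis$vegetation - 1.5 * basis$signature
  px <- which(scene$truth$mask, arr.ind = TRUE)[1, ]
  expect_equal(cal$data[px[1], px[2], ], expected_plant, tolerance = 1e-12)
})

test_that("plant reflectance inside the absorption window decreases with concentration", {
  lo <- noiseless_scene(concentration = 0.5, seed = 21)
  hi <- noiseless_scene(concentration = 2.0, seed = 21)
  window_mean <- function(scene) {
    cal <- calibrate_reflectance(scene$cube, scene$refs)
    wl <- cal$wavelengths_nm
    bidx <- wl >= 1110 & wl <= 1130
    mean(apply(cal$data[, , bidx, drop = FALSE], 3, function(sl) {
      mean(sl[scene$truth$mask])
    }))
  }
  expect_lt(window_mean(hi), window_mean(lo))
})

test_that("single-disk footprint matches the disk inequality evaluated directly", {
  sp <- scene_spec(n_leaves = 0L, plant_radius = 12, seed = 5L)
  scene <- generate_scene(sp)
  # reconstruct the seeded centre draw, then count pixels by brute force
  centre <- with_seed2(sp$seed + 1L, {
    c(sp$image_height / 2 + runif(1, -2, 2), sp$image_width / 2 + runif(1, -2, 2))
  })
  count <- 0L
  for (i in seq_len(sp$image_height)) for (j in seq_len(sp$image_width)) {
    if ((i - centre[1])^2 + (j - centre[2])^2 <= 12^2) count <- count + 1L
  }
  expect_identical(sum(scene$truth$mask), count)
})

test_that("scene generation is a pure function of its spec", {
  sp <- scene_spec(seed = 31L, concentration = 1.2)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$truth$mask, s2$truth$mask)
})

test_that("excessive concentration clips latent reflectance with a warning", {
  sp <- scene_spec(concentration = 40, seed = 2L, noise_sd = 0,
                   scatter_gain_sd = 0, scatter_offset_sd = 0)
  expect_warning(generate_scene(sp), "clipping")
})

test_that("cohorts have the declared design and are seed-deterministic", {
  cohort <- generate_cohort(n_conditions = 3L, plants_per_condition = 4L,
                            condition_means = c(1, 1.5, 2), plant_sd = 0.05,
                            seed = 8L)
  expect_identical(nrow(cohort$plants), 12L)
  expect_identical(nrow(cohort$reference), 3L)
  expect_identical(as.vector(table(cohort$plants$condition)), rep(4L, 3))

  again <- generate_cohort(n_conditions = 3L, plants_per_condition = 4L,
                           condition_means = c(1, 1.5, 2), plant_sd = 0.05,
                           seed = 8L)
  expect_identical(cohort$plants$true_concentration,
                   again$plants$true_concentration)
  expect_identical(purrr::map_int(cohort$plants$spec, "seed"),
                   purrr::map_int(again$plants$spec, "seed"))

  single <- generate_cohort(n_conditions = 1L, plants_per_condition = 1L,
                            condition_means = 1.3, plant_sd = 0, seed = 1L)
  expect_identical(single$plants$true_concentration, 1.3)
  expect_error(generate_cohort(1L, 1L, condition_means = -0.5, seed = 1L),
               class = "phenomap_error_parameter")
})

test_that("the reference table stores condition means, not per-plant truth", {
  cohort <- generate_cohort(n_conditions = 2L, plants_per_condition = 5L,
                            condition_means = c(1, 2), plant_sd = 0.1, seed = 3L)
  expect_identical(cohort$reference$total_phenolics_mg_per_g, c(1, 2))
  # per-plant truth varies around the mean and is retained separately
  expect_gt(stats::sd(cohort$plants$true_concentration[1:5]), 0)
})
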
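# Region partitions, mean-spectrum extraction, reference totals and splits.

test_that("region labelling is a partition of the mask", {
  scene <- generate_scene(scene_spec(image_height = 32L, image_width = 32L,
                                     plant_radius = 9, seed = 3L))
  mask <- scene$truth$mask
  lab <- partition_regions(mask, k = 10L, seed = 2L)
  expect_identical(!is.na(lab), mask)            # union = mask (and nothing else)
  expect_setequal(unique(lab[!is.na(lab)]), 1:10)  # every label non-empty
  # single region = whole mask
  lab1 <- partition_regions(mask, k = 1L, seed = 2L)
  expect_identical(lab1[mask], rep(1L, sum(mask)))
  # determinism and seed sensitivity (both remain partitions)
  expect_identical(partition_regions(mask, 10L, seed = 2L), lab)
  lab_b <- partition_regions(mask, 10L, seed = 3L)
  expect_identical(!is.na(lab_b), mask)
  # too few pixels
  tiny <- matrix(FALSE, 4, 4); tiny[1:2, 1] <- TRUE
  expect_error(partition_regions(tiny, k = 10L, seed = 1L),
               class = "phenomap_error_insufficient_pixels")
  expect_error(partition_regions(matrix(FALSE, 4, 4), k = 1L, seed = 1L),
               class = "phenomap_error_empty_mask")
})

test_that("random-assignment partitions are also exhaustive and disjoint", {
  m <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3)
  lab <- partition_regions(m, k = 2L, seed = 9L, method = "random")
  expect_identical(!is.na(lab), m)
  expect_setequal(unique(lab[!is.na(lab)]), 1:2)
})

test_that("mean spectra are exact region averages", {
  wl <- c(1000, 1100, 1200, 1300)
  # constant cube -> constant mean spectra
  cube <- hypercube(array(0.4, c(3, 3, 4)), wl, "SWIR", calibrated = TRUE)
  lab <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L, NA, NA, NA), 3, 3)
  tb <- extract_mean_spectra(cube, lab)
  expect_identical(nrow(tb), 3L)
  expect_true(all(abs(spectra_matrix(tb) - 0.4) < 1e-15))
  # two-pixel region mean = (u + v) / 2 exactly
  u <- c(0.1, 0.2, 0.3, 0.4); v <- c(0.5, 0.6, 0.7, 0.8)
  arr <- array(NA_real_, c(1, 2, 4)); arr[1, 1, ] <- u; arr[1, 2, ] <- v
  cube2 <- hypercube(arr, wl, "SWIR", calibrated = TRUE)
  lab2 <- matrix(c(1L, 1L), 1, 2)
  expect_equal(as.numeric(spectra_matrix(extract_mean_spectra(cube2, lab2))),
               (u + v) / 2)
})

test_that("pixel-weighted region means reconstruct the whole-plant mean", {
  scene <- generate_scene(scene_spec(image_height = 32L, image_width = 32L,
                                     plant_radius = 9, seed = 4L))
  cube <- calibrate_reflectance(scene$cube, scene$refs)
  lab <- partition_regions(scene$truth$mask, k = 7L, seed = 1L)
  tb <- extract_mean_spectra(cube, lab)
  counts <- as.vector(table(lab[!is.na(lab)]))
  weighted <- colSums(spectra_matrix(tb) * counts) / sum(counts)
  d <- dim(cube$data)
  pixmat <- matrix(cube$data, d[1] * d[2], d[3])[which(scene$truth$mask), ]
  expect_equal(weighted, unname(colMeans(pixmat)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("compound totals reproduce group sums with ND treated as zero", {
  tbl <- tibble::tibble(
    compound = c("a", "b", "c"),
    cond1 = c("0.5", "ND", "0.25"),
    cond2 = c("ND", "ND", "ND")
  )
  tot <- total_phenolics(tbl)
  expect_equal(tot$total_phenolics_mg_per_g, c(0.75, 0))
  # permutation invariance in compound order
  tot2 <- total_phenolics(tbl[c(3, 1, 2), ])
  expect_equal(tot2, tot)
  # additivity under table concatenation
  tot3 <- total_phenolics(dplyr::bind_rows(tbl, tbl))
  expect_equal(tot3$total_phenolics_mg_per_g, 2 * tot$total_phenolics_mg_per_g)
  expect_error(total_phenolics(tibble::tibble(compound = "a", c1 = "-0.1")),
               class = "phenomap_error_invalid_table")
  expect_error(total_phenolics(tibble::tibble(compound = "a", c1 = "oops")),
               class = "phenomap_error_invalid_table")
})

test_that("reference assignment joins totals by condition and is label-invariant", {
  x <- matrix(runif(8), 2, 4)
  tb <- make_table(x, c(1000, 1100, 1200, 1300), condition = c("c1", "c2"))
  totals <- tibble::tibble(condition = c("c1", "c2"),
                           total_phenolics_mg_per_g = c(1.2, 2.3))
  out <- assign_reference(tb, totals)
  expect_equal(out$y, c(1.2, 2.3))
  # consistent renaming leaves y unchanged
  tb2 <- dplyr::mutate(tb, condition = paste0("X_", condition))
  totals2 <- dplyr::mutate(totals, condition = paste0("X_", condition))
  expect_equal(assign_reference(tb2, totals2)$y, out$y)
  expect_error(assign_reference(dplyr::mutate(tb, condition = "unknown"), totals),
               class = "phenomap_error_lookup")
})

test_that("70:30 spectrum-level split yields 840/360 on 1,200 rows", {
  x <- matrix(runif(1200 * 3), 1200, 3)
  tb <- make_table(x, c(1000, 1100, 1200),
                   plant_id = rep(sprintf("plant_%03d", 1:120), each = 10),
                   region_id = rep(1:10, times = 120))
  sp <- split_calibration_validation(tb, 0.7, seed = 1L)
  expect_identical(sum(sp$split == "cal"), 840L)
  expect_identical(sum(sp$split == "val"), 360L)
  expect_identical(split_calibration_validation(tb, 0.7, seed = 1L)$split,
                   sp$split)
})

test_that("plant-level splits never share a plant across partitions", {
  x <- matrix(runif(40 * 3), 40, 3)
  tb <- make_table(x, c(1000, 1100, 1200),
                   plant_id = rep(sprintf("p%02d", 1:10), each = 4),
                   region_id = rep(1:4, times = 10))
  sp <- split_calibration_validation(tb, 0.7, seed = 2L, level = "plant")
  overlap <- intersect(unique(sp$plant_id[sp$split == "cal"]),
                       unique(sp$plant_id[sp$split == "val"]))
  expect_length(overlap, 0L)
  expect_error(split_calibration_validation(tb, 1.0, seed = 1L),
               class = "phenomap_error_parameter")
})
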
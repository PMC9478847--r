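# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# Desk-scale cohort: 8 conditions x 2 plants, 32 px scenes, default noise.
small_fixture <- function(seed = 42L) {
  key <- paste0("small_", seed)
  if (is.null(.fixtures[[key]])) {
    cohort <- generate_cohort(plants_per_condition = 2L, seed = seed,
                              image_height = 32L, image_width = 32L,
                              plant_radius = 9)
    table <- extract_cohort_spectra(cohort, seed = seed)
    table <- split_calibration_validation(table, 0.7, seed = seed)
    .fixtures[[key]] <- list(cohort = cohort, table = table)
  }
  .fixtures[[key]]
}

# One default-sized zero-noise, zero-scatter scene (analytic reflectance).
noiseless_scene <- function(concentration = 1.5, seed = 7L, n_leaves = 6L) {
  generate_scene(scene_spec(concentration = concentration, seed = seed,
                            n_leaves = n_leaves, noise_sd = 0,
                            scatter_gain_sd = 0, scatter_offset_sd = 0))
}

# Small seeded cube with float32-exact values for I/O round trips.
f32_cube <- function(h = 4L, w = 4L, b = 8L, seed = 3L) {
  vals <- with_seed2(seed, sample(0:1023, h * w * b, replace = TRUE) / 1024)
  hypercube(array(vals, dim = c(h, w, b)),
            seq(1000, by = 10, length.out = b), "SWIR", calibrated = TRUE)
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Wide spectra table from a plain matrix, for dataset-level tests.
make_table <- function(x, wavelengths, plant_id = NULL, region_id = NULL,
                       condition = "c1", y = NA_real_, split = "unassigned") {
  n <- nrow(x)
  meta <- tibble::tibble(
    plant_id = plant_id %||% sprintf("plant_%03d", seq_len(n)),
    region_id = region_id %||% rep(1L, n),
    condition = rep_len(condition, n),
    y = rep_len(y, n),
    split = rep_len(split, n)
  )
  colnames(x) <- as.character(wavelengths)
  dplyr::bind_cols(meta, tibble::as_tibble(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
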
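#' Specification of a synthetic plant scene
#'
#' Describes one simulated hyperspectral acquisition of a potted rosette
#' plant: image geometry, spectral grid, plant size and shape, the plant's
#' true total phenolic concentration, and the optical noise model. Defaults
#' follow the acquisition emulated throughout the package: a 64 x 64 px
#' scene; SWIR cubes span 900-2,500 nm in 161 bands, VIS/NIR cubes span
#' 400-1,000 nm in 121 bands.
#'
#' The plant canopy is rendered as a rosette of `n_leaves` overlapping
#' disks around a central disk (set `n_leaves = 0` for a single disk).
#' Per-pixel reflectance follows an affine scatter model,
#' `a * (baseline - concentration * signature) + b` with
#' `a ~ N(1, scatter_gain_sd)` and `b ~ N(0, scatter_offset_sd)` — exactly
#' the distortion family that MSC and SNV pretreatments are designed to
#' remove. Raw counts are `dark + latent * (white - dark) + N(0, noise_sd)`.
#'
#' @param range_tag `"SWIR"` or `"VISNIR"`.
#' @param image_height,image_width Scene size in pixels.
#' @param n_bands Number of spectral bands (>= 8).
#' @param wavelength_lo,wavelength_hi Grid endpoints in nm; default to the
#'   sensor span for the range tag.
#' @param plant_radius Canopy radius in pixels.
#' @param n_leaves Rosette leaf count (0 = single disk).
#' @param concentration True total phenolic content, mg/g dry weight.
#' @param condition_label Growing-condition label carried into the truth.
#' @param scatter_gain_sd,scatter_offset_sd SDs of the per-pixel
#'   multiplicative/additive scatter terms.
#' @param noise_sd SD of additive Gaussian sensor noise (count units).
#' @param seed Integer seed; scenes are pure functions of their spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(range_tag = c("SWIR", "VISNIR"),
                       image_height = 64L, image_width = 64L,
                       n_bands = NULL, wavelength_lo = NULL, wavelength_hi = NULL,
                       plant_radius = 18, n_leaves = 6L,
                       concentration = 1.5, condition_label = "unlabelled",
                       scatter_gain_sd = 0.05, scatter_offset_sd = 0.01,
                       noise_sd = 0.01, seed = 1L) {
  range_tag <- match.arg(range_tag)
  if (is.null(wavelength_lo)) wavelength_lo <- if (range_tag == "SWIR") 900 else 400
  if (is.null(wavelength_hi)) wavelength_hi <- if (range_tag == "SWIR") 2500 else 1000
  if (is.null(n_bands)) n_bands <- if (range_tag == "SWIR") 161L else 121L
  if (n_bands < 8L) {
    abort_phenomap("`n_bands` must be >= 8", "phenomap_error_parameter")
  }
  if (wavelength_lo >= wavelength_hi) {
    abort_phenomap("`wavelength_lo` must be < `wavelength_hi`",
                   "phenomap_error_parameter")
  }
  if (concentration < 0) {
    abort_phenomap("`concentration` must be >= 0", "phenomap_error_parameter")
  }
  if (noise_sd < 0 || scatter_gain_sd < 0 || scatter_offset_sd < 0) {
    abort_phenomap("noise/scatter SDs must be >= 0", "phenomap_error_parameter")
  }
  structure(
    list(range_tag = range_tag,
         image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         n_bands = as.integer(n_bands),
         wavelength_lo = wavelength_lo, wavelength_hi = wavelength_hi,
         plant_radius = plant_radius, n_leaves = as.integer(n_leaves),
         concentration = concentration, condition_label = condition_label,
         scatter_gain_sd = scatter_gain_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

range_span <- function(range_tag) {
  if (range_tag == "SWIR") c(900, 2500) else c(400, 1000)
}

#' Endmember spectra for synthetic scenes
#'
#' Builds the spectral building blocks of a scene on a given wavelength
#' grid: a smooth vegetation baseline (chlorophyll edge in VIS/NIR; water
#' absorption near 1,450 and 1,940 nm in SWIR), soil and pot backgrounds,
#' the white/dark reference levels, and a non-negative phenolic absorption
#' signature expressed per mg/g DW. The signature's peaks sit in the CH
#' overtone windows associated with phenolic compounds: 1,110-1,130 nm
#' (second overtone) and 1,645-1,670 nm (first overtone) in SWIR, and
#' 450-475 / 535-565 nm in VIS/NIR. Small seeded perturbations emulate
#' plant-to-plant biological variation.
#'
#' @param wavelengths_nm Strictly increasing grid within the tag's span.
#' @param range_tag `"SWIR"` or `"VISNIR"`.
#' @param seed Integer seed.
#' @return A list with components `vegetation`, `soil`, `pot`, `signature`,
#'   `white_level`, `dark_level` (vectors on the grid) and the peak centres
#'   used for the signature.
#' @export
generate_basis_spectra <- function(wavelengths_nm,
                                   range_tag = c("SWIR", "VISNIR"),
                                   seed = 1L) {
  range_tag <- match.arg(range_tag)
  wl <- as.numeric(wavelengths_nm)
  if (any(diff(wl) <= 0)) {
    abort_phenomap("wavelength grid must be strictly increasing",
                   "phenomap_error_invalid_grid")
  }
  span <- range_span(range_tag)
  if (min(wl) < span[1L] - 1e-9 || max(wl) > span[2L] + 1e-9) {
    abort_phenomap(
      sprintf("grid outside the %s span (%g-%g nm)", range_tag, span[1L], span[2L]),
      "phenomap_error_invalid_grid"
    )
  }
  with_seed(seed, {
    j <- stats::rnorm(6L)
    if (range_tag == "SWIR") {
      veg <- 0.58 * (1 + 0.02 * j[1L]) -
        0.26 * (1 + 0.05 * j[2L]) * gaussian_peak(wl, 1450, 45) -
        0.38 * gaussian_peak(wl, 1940, 75) -
        0.06 * gaussian_peak(wl, 1200, 35) -
        1e-4 * pmax(wl - 2000, 0)
      soil <- 0.22 + 6e-5 * (wl - 900) -
        0.04 * (1 + 0.1 * j[3L]) * gaussian_peak(wl, 1940, 90)
      pot <- 0.10 + 1e-5 * (wl - 900)
      centre1 <- 1120 + 3 * tanh(j[4L])   # stays inside 1,110-1,130 nm
      centre2 <- 1657 + 4 * tanh(j[5L])   # stays inside 1,645-1,670 nm
      signature <- 0.030 * gaussian_peak(wl, centre1, 12) +
        0.024 * gaussian_peak(wl, centre2, 14)
      white_level <- 0.88 + 0.04 * sin((wl - 900) / 500)
      dark_level <- 0.05 + 2e-6 * (wl - 900)
    } else {
      veg <- 0.04 + 0.08 * (1 + 0.05 * j[1L]) * gaussian_peak(wl, 550, 28) +
        0.46 * stats::plogis((wl - 712) / 16) -
        0.03 * (1 + 0.05 * j[2L]) * gaussian_peak(wl, 975, 25)
      soil <- 0.12 + 2.5e-4 * (wl - 400)
      pot <- 0.08 + 5e-5 * (wl - 400)
      centre1 <- 462 + 3 * tanh(j[4L])    # stays inside 450-475 nm
      centre2 <- 550 + 4 * tanh(j[5L])    # stays inside 535-565 nm
      signature <- 0.012 * gaussian_peak(wl, centre1, 10) +
        0.010 * gaussian_peak(wl, centre2, 12)
      white_level <- 0.90 + 0.03 * sin((wl - 400) / 250)
      dark_level <- 0.05 + 2e-6 * (wl - 400)
    }
    list(vegetation = clamp(veg, 0.02, 0.95),
         soil = clamp(soil, 0.02, 0.95),
         pot = clamp(pot, 0.02, 0.95),
         signature = signature,
         white_level = white_level,
         dark_level = dark_level,
         signature_centres = c(centre1, centre2))
  })
}

# Paint the rosette footprint; returns logical H x W mask.
paint_rosette <- function(h, w, radius, n_leaves, centre, phase) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside_disk <- function(cy, cx, r) (yy - cy)^2 + (xx - cx)^2 <= r^2
  if (n_leaves == 0L) {
    return(inside_disk(centre[1L], centre[2L], radius))
  }
  mask <- inside_disk(centre[1L], centre[2L], 0.5 * radius)
  angles <- phase + 2 * pi * (seq_len(n_leaves) - 1L) / n_leaves
  for (a in angles) {
    cy <- centre[1L] + 0.55 * radius * sin(a)
    cx <- centre[2L] + 0.55 * radius * cos(a)
    mask <- mask | inside_disk(cy, cx, 0.45 * radius)
  }
  mask
}

#' Generate one synthetic scene
#'
#' Renders the raw hypercube, white and dark reference frames and the
#' ground truth for one plant according to a [scene_spec()]. The latent
#' plant reflectance at each canopy pixel is
#' `a * (vegetation - concentration * signature) + b`; background pixels
#' carry soil or pot spectra under the same scatter model. Raw counts are
#' `dark + latent * (white - dark)` plus Gaussian sensor noise, so applying
#' [calibrate_reflectance()] to a zero-noise scene recovers the latent
#' reflectance exactly.
#'
#' @param spec A [scene_spec()].
#' @return A list with components `cube` (raw [hypercube()]), `refs`
#'   ([reference_frames()]), and `truth` (list: `mask`, `concentration`,
#'   `condition_label`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_height; w <- spec$image_width; b <- spec$n_bands
  wl <- seq(spec$wavelength_lo, spec$wavelength_hi, length.out = b)
  basis <- generate_basis_spectra(wl, spec$range_tag, seed = spec$seed)
  with_seed(spec$seed + 1L, {
    centre <- c(h / 2 + stats::runif(1, -2, 2), w / 2 + stats::runif(1, -2, 2))
    phase <- stats::runif(1, 0, 2 * pi)
    mask <- paint_rosette(h, w, spec$plant_radius, spec$n_leaves, centre, phase)
    if (!any(mask)) {
      abort_phenomap("plant footprint is empty; increase `plant_radius`",
                     "phenomap_error_parameter")
    }
    pot_zone <- paint_rosette(h, w, 1.35 * spec$plant_radius, 0L, centre, 0) & !mask

    npx <- h * w
    base <- matrix(basis$soil, npx, b, byrow = TRUE)
    base[pot_zone, ] <- matrix(basis$pot, sum(pot_zone), b, byrow = TRUE)
    plant_spec <- basis$vegetation - spec$concentration * basis$signature
    base[mask, ] <- matrix(plant_spec, sum(mask), b, byrow = TRUE)

    gain <- stats::rnorm(npx, 1, spec$scatter_gain_sd)
    offset <- stats::rnorm(npx, 0, spec$scatter_offset_sd)
    latent <- base * gain + offset

    neg_plant <- sum(latent[mask, ] < 0)
    if (neg_plant > 0.01 * sum(mask) * b) {
      warning("concentration drives >1% of plant voxels below zero reflectance; clipping",
              call. = FALSE)
    }
    latent <- pmax(latent, 0)

    wd <- basis$white_level - basis$dark_level
    raw <- sweep(latent, 2L, wd, "*")
    raw <- sweep(raw, 2L, basis$dark_level, "+")
    if (spec$noise_sd > 0) {
      raw <- raw + stats::rnorm(length(raw), 0, spec$noise_sd)
    }
    cube_arr <- array(raw, dim = c(h, w, b))

    white <- array(rep(basis$white_level, each = npx), dim = c(h, w, b))
    dark <- array(rep(basis$dark_level, each = npx), dim = c(h, w, b))
    if (spec$noise_sd > 0) {
      white <- white + stats::rnorm(length(white), 0, spec$noise_sd)
      dark <- dark + stats::rnorm(length(dark), 0, spec$noise_sd)
    }

    list(cube = hypercube(cube_arr, wl, spec$range_tag, calibrated = FALSE),
         refs = reference_frames(white, dark),
         truth = list(mask = mask, concentration = spec$concentration,
                      condition_label = spec$condition_label))
  })
}

#' Generate a cohort of synthetic plants with a group-level reference table
#'
#' Emulates the study design the pipeline targets: plants grown under a set
#' of conditions (default: eight light x drought regimes), with the
#' wet-chemistry reference measured per condition group rather than per
#' plant. Per-plant true concentrations are drawn from
#' `N(condition mean, plant_sd)` (truncated at zero); the reference table
#' reports the condition mean, while per-plant truth is retained separately
#' for recovery tests. Scene specs are returned rather than rendered cubes
#' so cohorts of any size stay cheap to hold; render plants one at a time
#' with [generate_scene()].
#'
#' @param n_conditions Number of growing conditions.
#' @param plants_per_condition Plants per condition (default 15, giving the
#'   canonical 8 x 15 = 120-plant cohort).
#' @param condition_means Per-condition mean total phenolics (mg/g DW);
#'   defaults to the packaged HPLC reference totals
#'   (see [phenolic_reference_totals()]).
#' @param condition_labels Optional labels, recycled against
#'   `condition_means`.
#' @param plant_sd Within-condition SD of per-plant true totals (mg/g DW).
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @param ... Passed to [scene_spec()] (image size, noise, ...).
#' @return A list with `plants` (tibble: `plant_id`, `condition`,
#'   `true_concentration`, `spec` list-column) and `reference` (tibble:
#'   `condition`, `total_phenolics_mg_per_g`).
#' @export
generate_cohort <- function(n_conditions = 8L, plants_per_condition = 15L,
                            condition_means = NULL, condition_labels = NULL,
                            plant_sd = 0.05, seed = 1L, ...) {
  if (is.null(condition_means)) {
    totals <- phenolic_reference_totals()
    condition_means <- totals$total_phenolics_mg_per_g[seq_len(n_conditions)]
    if (is.null(condition_labels)) {
      condition_labels <- totals$condition[seq_len(n_conditions)]
    }
  }
  if (length(condition_means) != n_conditions) {
    abort_phenomap("`condition_means` must have length `n_conditions`",
                   "phenomap_error_parameter")
  }
  if (any(condition_means < 0)) {
    abort_phenomap("condition means must be >= 0", "phenomap_error_parameter")
  }
  if (n_conditions < 1L || plants_per_condition < 1L) {
    abort_phenomap("counts must be >= 1", "phenomap_error_parameter")
  }
  if (is.null(condition_labels)) {
    condition_labels <- paste0("condition_", seq_len(n_conditions))
  }
  n <- n_conditions * plants_per_condition
  with_seed(seed, {
    cond_idx <- rep(seq_len(n_conditions), each = plants_per_condition)
    true_c <- pmax(stats::rnorm(n, condition_means[cond_idx], plant_sd), 0)
    scene_seeds <- sample.int(.Machine$integer.max - 2L, n)
    plants <- tibble::tibble(
      plant_id = sprintf("plant_%03d", seq_len(n)),
      condition = condition_labels[cond_idx],
      true_concentration = true_c,
      spec = purrr::pmap(
        list(true_c, condition_labels[cond_idx], scene_seeds),
        function(conc, lab, s) {
          scene_spec(concentration = conc, condition_label = lab,
                     seed = s, ...)
        }
      )
    )
    reference <- tibble::tibble(
      condition = condition_labels,
      total_phenolics_mg_per_g = condition_means
    )
    list(plants = plants, reference = reference)
  })
}
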
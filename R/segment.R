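#' Three-band composite image
#'
#' Extracts the three bands nearest to the requested target wavelengths
#' (ties broken toward the lower wavelength) and stacks them as an
#' H x W x 3 image. The canonical composites for canopy segmentation are
#' 947, 1,535 and 1,946 nm for SWIR cubes and 560, 655 and 750 nm for
#' VIS/NIR cubes.
#'
#' @param cube A [hypercube()].
#' @param targets Numeric length-3 vector of target wavelengths (nm).
#' @return H x W x 3 numeric array with attribute `wavelengths` (the band
#'   centres actually used).
#' @export
composite_bands <- function(cube, targets) {
  stopifnot(inherits(cube, "hypercube"), length(targets) == 3L)
  wl <- cube$wavelengths_nm
  spacing <- stats::median(diff(wl))
  idx <- vapply(targets, function(t) {
    if (t < min(wl) - spacing / 2 || t > max(wl) + spacing / 2) {
      abort_phenomap(sprintf("target %g nm is outside the cube span", t),
                     "phenomap_error_out_of_span")
    }
    which.min(abs(wl - t))  # ties resolve to the first (lower) wavelength
  }, integer(1))
  out <- cube$data[, , idx, drop = FALSE]
  attr(out, "wavelengths") <- wl[idx]
  attr(out, "band_indices") <- idx
  out
}

#' Segment the plant canopy from pot/soil background
#'
#' Computes a normalized-difference vegetation score between a
#' vegetation-bright and a water-absorption (background-bright) channel of
#' the three-band composite, thresholds it with Otsu's method, keeps the
#' largest connected component and fills small holes. All parameters are
#' recorded in `method_params` so a segmentation run is auditable.
#'
#' For SWIR cubes the composite is taken at 947/1,535/1,946 nm and the
#' score is `(R947 - R1946) / (R947 + R1946)`; for VIS/NIR it is taken at
#' 560/655/750 nm with score `(R750 - R655) / (R750 + R655)`.
#'
#' @param cube A calibrated [hypercube()].
#' @param targets Optional composite wavelengths (defaults per range tag).
#' @param threshold Optional manual score threshold overriding Otsu.
#' @param min_pixels Masks smaller than this raise an empty-mask error.
#' @return An object of class `plant_mask`: list with `mask` (logical
#'   H x W), `source_wavelengths`, `method_params`.
#' @export
segment_plant <- function(cube, targets = NULL, threshold = NULL,
                          min_pixels = 16L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated) {
    abort_phenomap("segmentation requires a calibrated cube",
                   "phenomap_error_state")
  }
  if (is.null(targets)) {
    targets <- if (cube$range_tag == "SWIR") c(947, 1535, 1946) else c(560, 655, 750)
  }
  comp <- composite_bands(cube, targets)
  if (cube$range_tag == "SWIR") {
    veg <- comp[, , 1L]; bg <- comp[, , 3L]
  } else {
    veg <- comp[, , 3L]; bg <- comp[, , 2L]
  }
  score <- (veg - bg) / (veg + bg + 1e-12)

  if (is.null(threshold)) {
    rng <- range(score)
    if (diff(rng) < 1e-12) {
      abort_phenomap("degenerate score image; no plant found",
                     "phenomap_error_empty_mask")
    }
    scaled <- (score - rng[1L]) / diff(rng)
    th_scaled <- EBImage::otsu(scaled, range = c(0, 1), levels = 256L)
    threshold <- rng[1L] + th_scaled * diff(rng)
    threshold_source <- "otsu"
  } else {
    threshold_source <- "manual"
  }
  mask <- score > threshold

  if (any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
    mask <- EBImage::fillHull(mask) > 0
  }
  if (sum(mask) < min_pixels) {
    abort_phenomap("segmentation produced an empty (or too small) mask",
                   "phenomap_error_empty_mask")
  }
  structure(
    list(mask = mask,
         source_wavelengths = attr(comp, "wavelengths"),
         method_params = list(score = "normalized_difference",
                              threshold = threshold,
                              threshold_source = threshold_source,
                              min_pixels = min_pixels,
                              cleanup = "largest_component+fill_holes")),
    class = "plant_mask"
  )
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d px (of %d), bands %s nm, threshold %.4f (%s)\n",
              sum(x$mask), length(x$mask),
              paste(round(x$source_wavelengths), collapse = "/"),
              x$method_params$threshold, x$method_params$threshold_source))
  invisible(x)
}

#' Export a plant mask as a 0/255 PNG with a JSON run record
#'
#' @param mask A `plant_mask`.
#' @param path Output PNG path; a `.json` sidecar is written alongside.
#' @return The PNG path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "plant_mask"))
  png::writePNG(mask$mask * 1, path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(source_wavelengths = mask$source_wavelengths,
         method_params = mask$method_params,
         n_pixels = sum(mask$mask)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
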
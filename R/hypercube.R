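#' Hyperspectral data cube
#'
#' A hypercube couples an H x W x B array (two spatial axes, one spectral
#' axis) with its wavelength grid in nanometres and a sensor-range tag.
#' Raw cubes hold detector counts; after [calibrate_reflectance()] the data
#' are relative reflectance and the `calibrated` flag is set.
#'
#' @param data Numeric H x W x B array (lines x samples x bands).
#' @param wavelengths_nm Strictly increasing numeric vector of length B (nm).
#' @param range_tag `"VISNIR"` (400-1,000 nm sensor) or `"SWIR"`
#'   (900-2,500 nm sensor).
#' @param calibrated Logical; `TRUE` once the cube holds reflectance.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm, range_tag = c("SWIR", "VISNIR"),
                      calibrated = FALSE) {
  range_tag <- match.arg(range_tag)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_phenomap("`data` must be a 3-D array (H x W x B)",
                   "phenomap_error_format")
  }
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3L]) {
    abort_phenomap("length of `wavelengths_nm` must equal the band extent of `data`",
                   "phenomap_error_format")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    abort_phenomap("`wavelengths_nm` must be strictly increasing",
                   "phenomap_error_format")
  }
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm,
         range_tag = range_tag, calibrated = isTRUE(calibrated)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d px, %d bands (%.0f-%.0f nm, %s), %s\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$range_tag, if (x$calibrated) "reflectance" else "raw counts"
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' White/dark reference frames
#'
#' Reference acquisitions used for reflectance calibration: a white frame
#' from a near-100%-reflective target and a dark frame with the shutter
#' closed. Frames may be full H x W x B stacks or single-line 1 x W x B
#' arrays; they are averaged across lines before use.
#'
#' @param white,dark Numeric arrays (H x W x B or 1 x W x B) or W x B matrices.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  as3d <- function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(1L, nrow(a), ncol(a)))
    if (!is.array(a) || length(dim(a)) != 3L) {
      abort_phenomap("reference frames must be arrays (H x W x B)",
                     "phenomap_error_format")
    }
    a
  }
  white <- as3d(white)
  dark <- as3d(dark)
  if (!all(dim(white)[2:3] == dim(dark)[2:3])) {
    abort_phenomap("white and dark frames must share sample/band extents",
                   "phenomap_error_format")
  }
  structure(list(white = white, dark = dark), class = "reference_frames")
}

# Average a reference stack across acquisition lines -> W x B matrix.
average_lines <- function(frame) {
  apply(frame, c(2L, 3L), mean)
}

#' Reflectance calibration against white/dark references
#'
#' Converts raw detector counts to relative reflectance with the standard
#' two-point correction: for every pixel and band,
#' \deqn{I_c = (I_h - I_d) / (I_w - I_d)} where \eqn{I_h} is the raw cube and
#' \eqn{I_w}, \eqn{I_d} the white and dark references (averaged across
#' acquisition lines). The result is clipped to `clip_range`; the number of
#' clipped voxels is recorded in the `clipped` attribute.
#'
#' @param raw An uncalibrated [hypercube()].
#' @param refs A [reference_frames()] object with shapes broadcastable to
#'   the cube.
#' @param eps Guard for the denominator; any band/sample position where the
#'   averaged white exceeds the averaged dark by less than `eps` raises a
#'   degenerate-reference error.
#' @param clip_range Length-2 numeric; reflectance outside this interval is
#'   clipped (counted, not dropped).
#' @return A calibrated [hypercube()] on the same grid.
#' @export
calibrate_reflectance <- function(raw, refs, eps = 1e-8, clip_range = c(0, 1.5)) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$calibrated) {
    abort_phenomap("cube is already calibrated", "phenomap_error_state")
  }
  d <- dim(raw$data)
  wm <- average_lines(refs$white)
  dm <- average_lines(refs$dark)
  if (!all(dim(wm) == d[2:3])) {
    abort_phenomap("reference frames are not broadcastable to the cube",
                   "phenomap_error_format")
  }
  denom <- wm - dm
  if (any(denom < eps)) {
    abort_phenomap("white and dark references coincide at one or more bands",
                   "phenomap_error_degenerate_reference")
  }
  out <- raw$data
  for (b in seq_len(d[3L])) {
    out[, , b] <- sweep(sweep(raw$data[, , b, drop = FALSE][, , 1L],
                              2L, dm[, b], "-"),
                        2L, denom[, b], "/")
  }
  n_clip <- sum(out < clip_range[1L] | out > clip_range[2L])
  if (n_clip > 0L) {
    out <- clamp(out, clip_range[1L], clip_range[2L])
  }
  cube <- hypercube(out, raw$wavelengths_nm, raw$range_tag, calibrated = TRUE)
  attr(cube, "clipped") <- n_clip
  cube
}

#' Trim to a wavelength window
#'
#' Retains exactly the bands with `lo <= wavelength <= hi`, preserving order.
#' Works on hypercubes and on wide spectra tables. Typical use follows the
#' sensor noise floors: 400-990 nm for VIS/NIR and 920-1,970 nm for SWIR.
#'
#' @param x A [hypercube()] or a spectra table.
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return The same kind of object restricted to the window.
#' @export
trim_wavelengths <- function(x, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi)) {
    abort_phenomap("`lo` must be < `hi`", "phenomap_error_parameter")
  }
  UseMethod("trim_wavelengths")
}

#' @export
trim_wavelengths.hypercube <- function(x, lo, hi) {
  keep <- which(x$wavelengths_nm >= lo & x$wavelengths_nm <= hi)
  if (length(keep) == 0L) {
    abort_phenomap("no bands fall inside the requested window",
                   "phenomap_error_empty_range")
  }
  out <- hypercube(x$data[, , keep, drop = FALSE], x$wavelengths_nm[keep],
                   x$range_tag, calibrated = x$calibrated)
  attr(out, "clipped") <- attr(x, "clipped")
  out
}

#' @export
trim_wavelengths.data.frame <- function(x, lo, hi) {
  wl <- spectra_wavelengths(x)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) {
    abort_phenomap("no bands fall inside the requested window",
                   "phenomap_error_empty_range")
  }
  drop_cols <- spectral_col_names(x)[!keep]
  x[, setdiff(names(x), drop_cols), drop = FALSE]
}

# Subset a cube to an integer band selection (used after waveband reduction).
subset_bands <- function(cube, indices) {
  stopifnot(inherits(cube, "hypercube"))
  if (any(indices < 1L | indices > length(cube$wavelengths_nm))) {
    abort_phenomap("band indices out of range", "phenomap_error_parameter")
  }
  hypercube(cube$data[, , indices, drop = FALSE], cube$wavelengths_nm[indices],
            cube$range_tag, calibrated = cube$calibrated)
}
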
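#' Chemical concentration image
#'
#' Applies a fitted phenolics model at every canopy pixel of a calibrated
#' cube: each pixel spectrum is pretreated exactly as the training spectra
#' were (same frozen MSC reference, same SG window), restricted to any
#' waveband selection, and mapped through the regression vector:
#' `value = (x - x_center) . K * L + intercept`. Off-canopy pixels carry
#' `NA`; pixels whose pretreatment is undefined (e.g. SNV of a constant
#' spectrum) are flagged, counted and also set to `NA`.
#'
#' The display constant `L` defaults to 1 so map units stay mg/g dry
#' weight; other values rescale the concentration term for display only.
#'
#' @param cube A calibrated [hypercube()] on the model's full band grid
#'   (trim before calling).
#' @param mask A `plant_mask` (or logical matrix).
#' @param model A `phenomap_model`.
#' @param L Display scale constant.
#' @return An object of class `chemical_image`: list with `map` (H x W,
#'   mg/g, `NA` off-canopy), `L`, `n_flagged`, `model_info`.
#' @export
apply_model_to_cube <- function(cube, mask, model, L = 1) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "phenomap_model"))
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  d <- dim(cube$data)
  if (!all(dim(m) == d[1:2])) {
    abort_phenomap("mask shape does not match the cube", "phenomap_error_format")
  }
  wl <- cube$wavelengths_nm
  if (length(wl) != length(model$wavelengths_full) ||
      max(abs(wl - model$wavelengths_full)) > 1e-6) {
    abort_phenomap("cube grid does not match the model's band grid",
                   "phenomap_error_grid")
  }
  px <- which(m)
  if (length(px) == 0L) {
    abort_phenomap("mask is empty", "phenomap_error_empty_mask")
  }
  pixmat <- matrix(cube$data, d[1L] * d[2L], d[3L])[px, , drop = FALSE]

  # screen pixels whose pretreatment is undefined before the vectorised call
  ok <- rep(TRUE, nrow(pixmat))
  meth <- model$preprocess$method
  if (meth == "mean_norm") ok <- abs(rowMeans(pixmat)) > 1e-12
  if (meth == "max_norm") ok <- abs(apply(pixmat, 1L, max)) > 1e-12
  if (meth %in% c("range_norm", "snv")) {
    ok <- apply(pixmat, 1L, max) - apply(pixmat, 1L, min) > 1e-12
  }
  n_flagged <- sum(!ok)
  if (n_flagged > 0L) {
    warning(sprintf("%d pixel(s) had degenerate spectra and were flagged", n_flagged),
            call. = FALSE)
  }
  vals <- rep(NA_real_, nrow(pixmat))
  if (any(ok)) {
    xp <- preprocess_apply(model$preprocess, pixmat[ok, , drop = FALSE])
    if (!is.null(model$selection)) {
      xp <- xp[, model$selection$selected_indices, drop = FALSE]
    }
    core <- model$core
    centred <- sweep(xp, 2L, core$x_center) %*% core$coefficients
    vals[ok] <- as.numeric(centred) * L + core$y_center
  }
  map <- matrix(NA_real_, d[1L], d[2L])
  map[px] <- vals
  structure(
    list(map = map, L = L, n_flagged = n_flagged,
         model_info = list(preprocess = meth, n_lv = model$core$n_lv,
                           n_bands = length(model$wavelengths))),
    class = "chemical_image"
  )
}

#' @export
print.chemical_image <- function(x, ...) {
  v <- x$map[is.finite(x$map)]
  cat(sprintf("<chemical_image> %d canopy px, %.3f-%.3f mg/g (mean %.3f)\n",
              length(v), min(v), max(v), mean(v)))
  invisible(x)
}

#' Whole-plant prediction from a chemical image
#'
#' Mean and dispersion of the mapped concentration over valid canopy
#' pixels — the per-plant value compared against the group-level
#' wet-chemistry reference.
#'
#' @param image A `chemical_image`.
#' @return One-row tibble: `mean_mg_per_g`, `sd_mg_per_g`, `n_pixels`.
#' @export
plant_prediction <- function(image) {
  stopifnot(inherits(image, "chemical_image"))
  v <- image$map[is.finite(image$map)]
  if (length(v) == 0L) {
    abort_phenomap("chemical image has no valid pixels", "phenomap_error_empty_map")
  }
  tibble::tibble(
    mean_mg_per_g = mean(v),
    sd_mg_per_g = if (length(v) > 1L) stats::sd(v) else 0,
    n_pixels = length(v)
  )
}

#' Render a chemical image to PNG
#'
#' Deterministic rendering with a blue-to-red palette over a stated value
#' range (default: the map's own range); background/flagged pixels render
#' neutral grey. The value range is written to a JSON sidecar so the
#' colour scale is auditable.
#'
#' @param image A `chemical_image`.
#' @param path Output PNG path.
#' @param value_range Length-2 range anchoring the palette; defaults to
#'   the finite map range.
#' @param n_colors Palette resolution.
#' @return Invisibly, a list with the palette range actually used.
#' @export
render_map <- function(image, path, value_range = NULL, n_colors = 256L) {
  stopifnot(inherits(image, "chemical_image"))
  v <- image$map
  finite <- is.finite(v)
  if (!any(finite)) {
    abort_phenomap("chemical image has no valid pixels", "phenomap_error_empty_map")
  }
  if (is.null(value_range)) value_range <- range(v[finite])
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(n_colors)
  idx <- pmin(pmax(ceiling((v - value_range[1L]) /
                             max(diff(value_range), 1e-12) * n_colors), 1L),
              n_colors)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  h <- nrow(v); w <- ncol(v)
  img <- array(0.85, dim = c(h, w, 3L))  # neutral grey background
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[finite] <- rgb[ch, finite]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  jsonlite::write_json(
    list(value_range = value_range,
         map_range = range(v[finite]),
         n_pixels = sum(finite), L = image$L),
    sub("\\.png$", ".json", path), auto_unbox = TRUE, digits = NA
  )
  invisible(list(path = path, value_range = value_range))
}
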
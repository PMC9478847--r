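#' Orthonormal discrete cosine transform (DCT-II)
#'
#' `c_k = s_k * sum_n x_n cos(pi (2n + 1) k / (2N))` with
#' `s_0 = sqrt(1/N)` and `s_k = sqrt(2/N)` for `k > 0`, so the transform
#' is orthonormal (Parseval: `sum x^2 = sum c^2`) and coefficient 1 (the
#' DC term) equals `mean(x) * sqrt(N)`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of DCT coefficients, same length.
#' @export
dct2 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) abort_phenomap("empty vector", "phenomap_error_parameter")
  as.numeric(dct_matrix(n) %*% x)
}

dct_matrix_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(dct_matrix_cache[[key]])) return(dct_matrix_cache[[key]])
  k <- 0:(n - 1L)
  m <- outer(k, k, function(k, j) cos(pi * (2 * j + 1) * k / (2 * n)))
  m <- m * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  dct_matrix_cache[[key]] <- m
  m
}

#' Per-waveband DCT energy scores
#'
#' The waveband-reduction statistic: for each band, take the vector of
#' that band's values across the calibration spectra (rows in fixed
#' dataset order), transform it with the DCT, discard the DC coefficient
#' (it carries only the band's mean level) and the high-frequency tail of
#' the AC coefficients (edge-like features), and score the band by the
#' largest absolute retained AC coefficient. Bands whose across-sample
#' variation tracks the reference chemistry concentrate energy in the
#' retained low-frequency AC coefficients and score high.
#'
#' @param x_cal Calibration spectra matrix (rows = spectra, in the order
#'   they were assembled; the scores are order-sensitive, so serialize the
#'   order with any saved selection).
#' @param hf_cut Fraction of the highest-frequency AC coefficients to
#'   discard (default 0.5 = drop the upper half).
#' @param axis `"samples"` (default; the transform runs across spectra,
#'   one coefficient set per waveband) or `"bands"` (per-spectrum
#'   transform across wavebands, provided for comparison).
#' @return Numeric vector of per-band scores (length B).
#' @export
band_scores <- function(x_cal, hf_cut = 0.5, axis = c("samples", "bands")) {
  axis <- match.arg(axis)
  x <- as.matrix(x_cal)
  if (axis == "bands") x <- t(x)
  n <- nrow(x)
  if (n < 4L) {
    abort_phenomap("need at least 4 calibration spectra", "phenomap_error_parameter")
  }
  n_ac <- n - 1L
  n_keep <- floor(n_ac * (1 - hf_cut))
  if (n_keep < 1L) {
    abort_phenomap("hf_cut leaves no retained AC coefficients",
                   "phenomap_error_insufficient_rows")
  }
  coeffs <- dct_matrix(n) %*% x            # rows = coefficients, cols = bands
  retained <- coeffs[2:(1L + n_keep), , drop = FALSE]
  apply(abs(retained), 2L, max)
}

#' Peak-pick the selected wavebands from band scores
#'
#' Selects the local maxima of the score vector with prominence at least
#' `min_prominence` and pairwise index separation at least
#' `min_separation`. Endpoints are eligible; a plateau contributes its
#' left-most index; when two peaks violate the separation the higher one
#' wins. A strictly constant score vector has no peaks.
#'
#' @param scores Numeric per-band score vector.
#' @param min_prominence Absolute prominence threshold; default 5% of the
#'   score range.
#' @param min_separation Minimum index distance between selected peaks.
#' @return An object of class `band_selection`: list with `scores`,
#'   `selected_indices` (sorted, 1-based), `peak_params`, `dc_excluded`,
#'   `hf_cut` (the latter two filled by [select_wavebands()]).
#' @export
select_bands <- function(scores, min_prominence = NULL, min_separation = 1L) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) {
    abort_phenomap("scores must be finite", "phenomap_error_parameter")
  }
  if (is.null(min_prominence)) min_prominence <- 0.05 * diff(range(scores))
  peaks <- find_peaks(scores)
  if (length(peaks) > 0L) {
    prom <- vapply(peaks, function(i) peak_prominence(scores, i), numeric(1))
    keep <- prom >= min_prominence & prom > 0
    peaks <- peaks[keep]
    prom <- prom[keep]
    if (length(peaks) > 1L && min_separation > 1L) {
      ord <- order(scores[peaks], decreasing = TRUE)
      chosen <- integer(0)
      for (i in peaks[ord]) {
        if (all(abs(i - chosen) >= min_separation)) chosen <- c(chosen, i)
      }
      peaks <- sort(chosen)
    }
  }
  structure(
    list(scores = scores, selected_indices = sort(unique(peaks)),
         dc_excluded = TRUE, hf_cut = NA_real_,
         peak_params = list(min_prominence = min_prominence,
                            min_separation = as.integer(min_separation))),
    class = "band_selection"
  )
}

# Local maxima with plateau handling: a maximal run of equal values is a
# peak iff every existing neighbour is strictly lower; the run's left-most
# index represents it. Endpoints are eligible; a fully constant vector has
# no neighbours and therefore no peaks.
find_peaks <- function(s) {
  n <- length(s)
  if (n < 2L) return(integer(0))
  runs <- rle(s)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  peaks <- integer(0)
  for (r in seq_along(runs$values)) {
    left_ok <- r == 1L || runs$values[r - 1L] < runs$values[r]
    right_ok <- r == length(runs$values) || runs$values[r + 1L] < runs$values[r]
    has_neighbour <- length(runs$values) > 1L
    if (left_ok && right_ok && has_neighbour) peaks <- c(peaks, starts[r])
  }
  peaks
}

# Prominence: height above the higher of the two valley floors reached
# before a strictly higher value (or the series end) on each side.
peak_prominence <- function(s, i) {
  left <- if (i == 1L) s[i] else {
    j <- i - 1L; lo <- s[j]
    while (j >= 1L && s[j] <= s[i]) { lo <- min(lo, s[j]); j <- j - 1L }
    lo
  }
  right <- if (i == length(s)) s[i] else {
    j <- i + 1L; lo <- s[j]
    while (j <= length(s) && s[j] <= s[i]) { lo <- min(lo, s[j]); j <- j + 1L }
    lo
  }
  base <- if (i == 1L) right else if (i == length(s)) left else max(left, right)
  s[i] - base
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %d of %d bands selected\n",
              length(x$selected_indices), length(x$scores)))
  invisible(x)
}

#' Score and select wavebands from a split spectra table
#'
#' Convenience wrapper tying the pieces together: pretreats the table
#' (frozen on calibration rows), computes [band_scores()] on the
#' calibration partition only, and peak-picks the selection. Wavelengths
#' of the selected bands are attached.
#'
#' @param table A split spectra table.
#' @param preprocess A [preprocess_spec()].
#' @param hf_cut,axis Passed to [band_scores()].
#' @param min_prominence,min_separation Passed to [select_bands()].
#' @return A `band_selection` with `wavelengths_nm` filled in.
#' @export
select_wavebands <- function(table, preprocess = preprocess_spec("raw"),
                             hf_cut = 0.5, axis = "samples",
                             min_prominence = NULL, min_separation = 1L) {
  cal <- table$split == "cal"
  if (!any(cal)) {
    abort_phenomap("table has no calibration rows", "phenomap_error_split")
  }
  x <- spectra_matrix(table)
  preprocess <- preprocess_fit(preprocess, x[cal, , drop = FALSE])
  xp <- preprocess_apply(preprocess, x[cal, , drop = FALSE])
  scores <- band_scores(xp, hf_cut = hf_cut, axis = axis)
  sel <- select_bands(scores, min_prominence = min_prominence,
                      min_separation = min_separation)
  sel$hf_cut <- hf_cut
  sel$wavelengths_nm <- spectra_wavelengths(table)[sel$selected_indices]
  sel$preprocess_method <- preprocess$method
  sel
}

#' Restrict a spectra table to the selected wavebands
#'
#' @param table A spectra table.
#' @param selection A `band_selection` (non-empty).
#' @return The table retaining exactly the selected wavelength columns,
#'   order preserved.
#' @export
reduce_dataset <- function(table, selection) {
  idx <- if (inherits(selection, "band_selection")) {
    selection$selected_indices
  } else {
    as.integer(selection)
  }
  if (length(idx) == 0L) {
    abort_phenomap("band selection is empty", "phenomap_error_selection")
  }
  spec_cols <- spectral_col_names(table)
  if (any(idx < 1L | idx > length(spec_cols))) {
    abort_phenomap("selection indices out of range", "phenomap_error_parameter")
  }
  keep <- c(meta_col_names(table), spec_cols[sort(unique(idx))])
  out <- table[, keep, drop = FALSE]
  attr(out, "band_selection") <- idx
  out
}

#' Serialize a band selection to JSON
#'
#' @param selection A `band_selection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_band_selection <- function(selection, path) {
  jsonlite::write_json(
    list(scores = selection$scores,
         selected_indices = selection$selected_indices,
         wavelengths_nm = selection$wavelengths_nm,
         hf_cut = selection$hf_cut,
         dc_excluded = selection$dc_excluded,
         peak_params = selection$peak_params),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
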
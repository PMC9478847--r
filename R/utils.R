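# Internal helpers shared across modules.

abort_phenomap <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "phenomap_error"), ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

gaussian_peak <- function(x, center, width) exp(-0.5 * ((x - center) / width)^2)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Spectral columns of a spectra table are named by their wavelength in nm.
is_wavelength_name <- function(nm) grepl("^[0-9]+(\\.[0-9]+)?$", nm)

#' Extract the spectral matrix from a spectra table
#'
#' Spectra tables are wide tibbles: metadata columns (`plant_id`, `region_id`,
#' `condition`, `y`, `split`) plus one numeric column per wavelength, named by
#' the wavelength in nanometres. These helpers pull out the n x B spectral
#' matrix and its wavelength grid.
#'
#' @param table A spectra table (tibble).
#' @return `spectra_matrix()`: a numeric matrix with one row per spectrum;
#'   `spectra_wavelengths()`: the numeric wavelength grid (nm).
#' @export
spectra_matrix <- function(table) {
  cols <- spectral_col_names(table)
  if (length(cols) == 0L) {
    abort_phenomap("table has no wavelength columns", "phenomap_error_format")
  }
  as.matrix(table[, cols, drop = FALSE])
}

#' @rdname spectra_matrix
#' @export
spectra_wavelengths <- function(table) {
  as.numeric(spectral_col_names(table))
}

spectral_col_names <- function(table) {
  names(table)[is_wavelength_name(names(table))]
}

meta_col_names <- function(table) {
  setdiff(names(table), spectral_col_names(table))
}

# Rebuild a wide spectra table from metadata columns + matrix + grid.
rebuild_spectra_table <- function(meta, mat, wavelengths_nm) {
  stopifnot(nrow(meta) == nrow(mat), ncol(mat) == length(wavelengths_nm))
  colnames(mat) <- format_wavelength(wavelengths_nm)
  dplyr::bind_cols(tibble::as_tibble(meta), tibble::as_tibble(mat))
}

format_wavelength <- function(wl) {
  ifelse(wl == round(wl), sprintf("%d", as.integer(round(wl))), sprintf("%g", wl))
}
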
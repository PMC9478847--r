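# ggplot2 helpers for the main result types.

#' Plot spectra coloured by a metadata column
#'
#' @param table A spectra table.
#' @param color_by Metadata column mapped to colour (default `condition`).
#' @param n_max Plot at most this many spectra (sampled deterministically).
#' @return A ggplot.
#' @export
plot_spectra <- function(table, color_by = "condition", n_max = 200L) {
  if (nrow(table) > n_max) {
    table <- table[round(seq(1L, nrow(table), length.out = n_max)), ]
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(table, .row = dplyr::row_number()),
    cols = dplyr::all_of(spectral_col_names(table)),
    names_to = "wavelength_nm", values_to = "value"
  )
  long$wavelength_nm <- as.numeric(long$wavelength_nm)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$value,
    group = .data$.row, color = .data[[color_by]]
  )) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "value") +
    ggplot2::theme_minimal()
}

#' Predicted vs reference plot for a fitted model
#'
#' @param object A `phenomap_model`.
#' @param table The spectra table it was fitted on.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phenomap_model
#' @export
autoplot.phenomap_model <- function(object, table, ...) {
  aug <- augment(object, table)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$y, y = .data$.pred,
                                    color = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "reference total phenolics (mg/g DW)",
                  y = "predicted (mg/g DW)") +
    ggplot2::theme_minimal()
}

#' Band-score profile with selected wavebands
#'
#' @param object A `band_selection` (with wavelengths attached).
#' @param wavelengths_nm Grid override if the selection lacks one.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot band_selection
#' @export
autoplot.band_selection <- function(object, wavelengths_nm = NULL, ...) {
  wl <- wavelengths_nm %||% seq_along(object$scores)
  if (!is.null(object$wavelengths_nm) && length(wl) == length(object$scores)) {
    sel_x <- wl[object$selected_indices]
  } else {
    sel_x <- object$selected_indices
  }
  df <- tibble::tibble(wavelength_nm = wl, score = object$scores)
  sel <- tibble::tibble(wavelength_nm = sel_x,
                        score = object$scores[object$selected_indices])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = sel, color = "red", size = 2) +
    ggplot2::labs(x = "wavelength (nm)", y = "max retained |AC| score") +
    ggplot2::theme_minimal()
}

#' Chemical-image raster with a blue-to-red concentration scale
#'
#' @param object A `chemical_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chemical_image
#' @export
autoplot.chemical_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$map)),
                           col = seq_len(ncol(object$map)))
  df$value <- as.vector(object$map)[(df$col - 1L) * nrow(object$map) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colors = c("blue", "cyan", "yellow", "red"),
      na.value = "grey85", name = "mg/g DW"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
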
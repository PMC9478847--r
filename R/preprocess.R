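#' Spectral pretreatment specification
#'
#' The eight row-wise pretreatments compared throughout the package:
#' `raw` (none), `mean_norm` (`x / mean(x)`), `max_norm` (`x / max(x)`),
#' `range_norm` (`(x - min) / (max - min)`), `msc` (multiplicative scatter
#' correction against a reference spectrum), `snv` (standard normal
#' variate), and `sg1` / `sg2` (Savitzky-Golay 1st/2nd derivatives).
#' All transforms are local to a row; MSC's reference is the only fitted
#' state and is frozen from calibration rows via [preprocess_fit()].
#'
#' Savitzky-Golay defaults: window 11 points, polynomial order 2 for the
#' first derivative and 3 for the second. Derivatives are per band index;
#' grids are uniform after trimming, and downstream regression is
#' scale-equivariant, so the wavelength-spacing factor is recorded rather
#' than applied.
#'
#' @param method One of `"raw"`, `"mean_norm"`, `"max_norm"`,
#'   `"range_norm"`, `"msc"`, `"snv"`, `"sg1"`, `"sg2"`.
#' @param sg_window Odd window length for SG filters.
#' @param sg_polyorder Polynomial order (< `sg_window`); defaults 2 (sg1)
#'   or 3 (sg2).
#' @param msc_reference Optional fixed reference spectrum for MSC; if
#'   `NULL` it is frozen as the calibration-mean spectrum at fit time.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("raw", "mean_norm", "max_norm",
                                       "range_norm", "msc", "snv", "sg1", "sg2"),
                            sg_window = 11L, sg_polyorder = NULL,
                            msc_reference = NULL) {
  method <- match.arg(method)
  if (is.null(sg_polyorder)) sg_polyorder <- if (method == "sg2") 3L else 2L
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder) {
    abort_phenomap("`sg_window` must be odd and > `sg_polyorder`",
                   "phenomap_error_parameter")
  }
  structure(
    list(method = method, sg_window = sg_window, sg_polyorder = sg_polyorder,
         msc_reference = msc_reference, fitted = !is.null(msc_reference) ||
           !(method == "msc")),
    class = "preprocess_spec"
  )
}

#' Freeze pretreatment state from calibration spectra
#'
#' For MSC, stores the calibration-mean spectrum as the correction
#' reference; all other methods are stateless and pass through unchanged.
#' Validation (and per-pixel) spectra are always corrected against this
#' frozen reference, never their own batch mean.
#'
#' @param spec A [preprocess_spec()].
#' @param x_cal Calibration spectra matrix (rows = spectra).
#' @return The spec with any fitted state attached.
#' @export
preprocess_fit <- function(spec, x_cal) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (spec$method == "msc" && is.null(spec$msc_reference)) {
    spec$msc_reference <- colMeans(x_cal)
  }
  spec$fitted <- TRUE
  spec
}

#' Apply a pretreatment to a spectra matrix
#'
#' @param spec A (fitted, for MSC) [preprocess_spec()].
#' @param x Spectra matrix or a single spectrum vector.
#' @return The transformed matrix (or vector, matching the input shape).
#' @export
preprocess_apply <- function(spec, x) {
  stopifnot(inherits(spec, "preprocess_spec"))
  vec_in <- is.null(dim(x))
  x <- rbind_matrix(x)
  out <- switch(spec$method,
    raw = x,
    mean_norm = {
      m <- rowMeans(x)
      check_degenerate(abs(m) > 1e-12, "zero-mean spectrum in mean normalization")
      x / m
    },
    max_norm = {
      m <- apply(x, 1L, max)
      check_degenerate(abs(m) > 1e-12, "zero-max spectrum in max normalization")
      x / m
    },
    range_norm = {
      lo <- apply(x, 1L, min); hi <- apply(x, 1L, max)
      check_degenerate(hi - lo > 1e-12, "constant spectrum in range normalization")
      (x - lo) / (hi - lo)
    },
    snv = snv(x),
    msc = {
      if (is.null(spec$msc_reference)) {
        abort_phenomap("MSC reference not fitted; call preprocess_fit() first",
                       "phenomap_error_state")
      }
      msc(x, spec$msc_reference)
    },
    sg1 = sg_derivative(x, order = 1L, window = spec$sg_window,
                        polyorder = spec$sg_polyorder),
    sg2 = sg_derivative(x, order = 2L, window = spec$sg_window,
                        polyorder = spec$sg_polyorder)
  )
  if (vec_in) drop(out) else out
}

rbind_matrix <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)

check_degenerate <- function(ok, msg) {
  if (!all(ok)) {
    abort_phenomap(paste0(msg, sprintf(" (%d row(s))", sum(!ok))),
                   "phenomap_error_degenerate_spectrum")
  }
  invisible(TRUE)
}

#' Standard normal variate
#'
#' Centers each spectrum and scales it to unit sample SD (n-1 divisor),
#' removing per-spectrum multiplicative and additive scatter.
#'
#' @param x Spectra matrix or vector.
#' @return Transformed spectra, same shape.
#' @export
snv <- function(x) {
  vec_in <- is.null(dim(x))
  x <- rbind_matrix(x)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  check_degenerate(s > 1e-12, "zero-SD spectrum in SNV")
  out <- (x - m) / s
  if (vec_in) drop(out) else out
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on the reference spectrum,
#' `x ~ a + b * reference`, and returns `(x - a) / b`, undoing per-spectrum
#' affine scatter.
#'
#' @param x Spectra matrix or vector.
#' @param reference Reference spectrum (typically the calibration mean).
#' @return Corrected spectra, same shape.
#' @export
msc <- function(x, reference) {
  vec_in <- is.null(dim(x))
  x <- rbind_matrix(x)
  ref <- as.numeric(reference)
  stopifnot(ncol(x) == length(ref))
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  if (denom < 1e-20) {
    abort_phenomap("constant MSC reference", "phenomap_error_degenerate_fit")
  }
  b <- as.vector((x - rowMeans(x)) %*% rc) / denom
  if (!all(abs(b) > 1e-10)) {
    abort_phenomap(sprintf("degenerate MSC fit (slope ~ 0) (%d row(s))",
                           sum(abs(b) <= 1e-10)),
                   "phenomap_error_degenerate_fit")
  }
  a <- rowMeans(x) - b * mean(ref)
  out <- (x - a) / b
  if (vec_in) drop(out) else out
}

#' Savitzky-Golay derivative
#'
#' Local least-squares polynomial differentiation along the spectral axis,
#' with edge points handled by the polynomial-fit extension (the fit at the
#' first/last window rather than zero padding). Output units are
#' reflectance per band index.
#'
#' @param x Spectra matrix or vector.
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length (<= band count).
#' @param polyorder Polynomial order (> `order`, < `window`).
#' @return Differentiated spectra, same shape.
#' @export
sg_derivative <- function(x, order = 1L, window = 11L, polyorder = NULL) {
  if (!order %in% c(1L, 2L)) {
    abort_phenomap("`order` must be 1 or 2", "phenomap_error_parameter")
  }
  if (is.null(polyorder)) polyorder <- if (order == 2L) 3L else 2L
  vec_in <- is.null(dim(x))
  x <- rbind_matrix(x)
  b <- ncol(x)
  if (window %% 2L == 0L || window <= polyorder || polyorder <= order) {
    abort_phenomap("need odd `window` > `polyorder` > `order`",
                   "phenomap_error_parameter")
  }
  if (window > b) {
    abort_phenomap(sprintf("window (%d) exceeds band count (%d)", window, b),
                   "phenomap_error_window")
  }
  op <- sg_operator(b, polyorder, window, order)
  out <- x %*% t(op)
  if (vec_in) drop(out) else out
}

# Dense B x B linear operator equivalent to signal::sgolayfilt; built once
# per (grid size, filter) and cached.
sg_operator_cache <- new.env(parent = emptyenv())
sg_operator <- function(b, p, n, m) {
  key <- paste(b, p, n, m, sep = "_")
  if (!is.null(sg_operator_cache[[key]])) return(sg_operator_cache[[key]])
  op <- vapply(seq_len(b), function(j) {
    e <- numeric(b); e[j] <- 1
    signal::sgolayfilt(e, p = p, n = n, m = m)
  }, numeric(b))
  # vapply over unit vectors gives columns = response to e_j, i.e. the operator
  sg_operator_cache[[key]] <- op
  op
}

#' The canonical set of pretreatment specs
#'
#' @return Named list of the eight [preprocess_spec()] objects.
#' @export
preprocess_methods <- function() {
  methods <- c("mean_norm", "max_norm", "range_norm", "msc", "snv",
               "sg1", "sg2", "raw")
  stats::setNames(lapply(methods, preprocess_spec), methods)
}

# TRUE if the pretreatment is a linear operator on spectra (so averaging
# commutes with it); MSC/SNV/normalizations are row-nonlinear.
is_linear_preprocess <- function(spec) spec$method %in% c("raw", "sg1", "sg2")
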
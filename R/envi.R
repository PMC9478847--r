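#' Read and write hypercubes as ENVI raster + header pairs
#'
#' A minimal, interoperable subset of the ENVI format: data types 4
#' (float32) and 12 (uint16), little-endian byte order, interleaves
#' `bsq`, `bil` and `bip`, with the wavelength grid (nm) carried in the
#' header's `wavelength` block. `write_envi()` produces `<path>.hdr` and
#' `<path>.raw`; `read_envi()` accepts the header path (or the bare stem).
#'
#' @param header_path Path to the `.hdr` file.
#' @param cube A [hypercube()].
#' @param path Output stem (without extension) or a `.hdr`/`.raw` path.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 12 (uint16).
#' @return `read_envi()`: a [hypercube()]; `write_envi()`: the header path,
#'   invisibly.
#' @export
read_envi <- function(header_path) {
  if (!grepl("\\.hdr$", header_path) && file.exists(paste0(header_path, ".hdr"))) {
    header_path <- paste0(header_path, ".hdr")
  }
  if (!file.exists(header_path)) {
    abort_phenomap(paste0("header not found: ", header_path), "phenomap_error_io")
  }
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0L) {
    abort_phenomap(paste0("header missing fields: ", paste(miss, collapse = ", ")),
                   "phenomap_error_format")
  }
  if (is.null(hdr[["wavelength"]])) {
    abort_phenomap("header has no wavelength block", "phenomap_error_format")
  }
  samples <- as.integer(hdr[["samples"]])
  lines <- as.integer(hdr[["lines"]])
  bands <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr[["interleave"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1L]])
  if (length(wl) != bands) {
    abort_phenomap("wavelength count does not match `bands`", "phenomap_error_format")
  }
  if (!interleave %in% c("bsq", "bil", "bip")) {
    abort_phenomap(paste0("unsupported interleave: ", interleave),
                   "phenomap_error_format")
  }
  if (!dtype %in% c(4L, 12L)) {
    abort_phenomap(paste0("unsupported data type: ", dtype), "phenomap_error_format")
  }
  data_path <- envi_data_path(header_path)
  n <- samples * lines * bands
  elt_size <- if (dtype == 4L) 4L else 2L
  if (file.size(data_path) != n * elt_size) {
    abort_phenomap("raster size does not match header dimensions",
                   "phenomap_error_corrupt_file")
  }
  con <- file(data_path, "rb")
  on.exit(close(con))
  vals <- if (dtype == 4L) {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
  }
  # File order (fastest first): bsq = sample, line, band; bil = sample, band,
  # line; bip = band, sample, line. Array layout is [line, sample, band].
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, dim = c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, dim = c(bands, samples, lines)), c(3L, 2L, 1L))
  )
  range_tag <- toupper(hdr[["range tag"]] %||% guess_range_tag(wl))
  calibrated <- identical(hdr[["calibrated"]], "1")
  hypercube(arr, wl, range_tag, calibrated = calibrated)
}

#' @rdname read_envi
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- as.integer(data_type)
  if (!data_type %in% c(4L, 12L)) {
    abort_phenomap("data type must be 4 (float32) or 12 (uint16)",
                   "phenomap_error_parameter")
  }
  stem <- sub("\\.(hdr|raw)$", "", path)
  d <- dim(cube$data)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube$data, c(3L, 2L, 1L)))
  )
  con <- file(paste0(stem, ".raw"), "wb")
  if (data_type == 4L) {
    writeBin(vals, con, size = 4L, endian = "little")
  } else {
    iv <- round(vals)
    if (any(abs(vals - iv) > 1e-6) || any(iv < 0) || any(iv > 65535)) {
      close(con)
      abort_phenomap("uint16 export requires integer values in [0, 65535]",
                     "phenomap_error_parameter")
    }
    writeBin(as.integer(iv), con, size = 2L, endian = "little")
  }
  close(con)
  hdr <- c(
    "ENVI",
    "description = {phenomap export}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("range tag = %s", cube$range_tag),
    sprintf("calibrated = %d", as.integer(cube$calibrated)),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.3f", cube$wavelengths_nm), collapse = ", "))
  )
  writeLines(hdr, paste0(stem, ".hdr"))
  invisible(paste0(stem, ".hdr"))
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # Join multi-line { ... } blocks before splitting into key = value pairs.
  joined <- character(0)
  buf <- NULL
  for (ln in lines) {
    if (is.null(buf)) {
      if (grepl("\\{", ln) && !grepl("\\}", ln)) buf <- ln else joined <- c(joined, ln)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) {
        joined <- c(joined, buf)
        buf <- NULL
      }
    }
  }
  joined <- joined[grepl("=", joined)]
  keys <- tolower(trimws(sub("=.*$", "", joined)))
  vals <- trimws(sub("^[^=]*=", "", joined))
  vals <- gsub("[{}]", "", vals)
  stats::setNames(as.list(trimws(vals)), keys)
}

envi_data_path <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path)
  for (ext in c(".raw", ".dat", ".img", "")) {
    p <- paste0(stem, ext)
    if (file.exists(p) && !identical(p, header_path)) return(p)
  }
  abort_phenomap(paste0("no raster file found for ", header_path),
                 "phenomap_error_io")
}

guess_range_tag <- function(wl) if (max(wl) > 1100) "SWIR" else "VISNIR"
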
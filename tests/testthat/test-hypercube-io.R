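# ENVI round trips and the white/dark reflectance correction.

test_that("ENVI write/read round-trips data and wavelengths for all interleaves", {
  cube <- f32_cube()
  for (il in c("bsq", "bil", "bip")) {
    stem <- file.path(withr::local_tempdir(), paste0("cube_", il))
    write_envi(cube, stem, interleave = il)
    back <- read_envi(paste0(stem, ".hdr"))
    expect_identical(back$data, cube$data, label = il)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm, tolerance = 1e-3)
    expect_identical(back$range_tag, cube$range_tag)
    expect_true(back$calibrated)
  }
})

test_that("an independently hand-encoded BIL file reads back as the same cube", {
  cube <- f32_cube(h = 3L, w = 5L, b = 4L, seed = 9L)
  stem <- file.path(withr::local_tempdir(), "oracle_bil")
  # independent encoder: explicit loops, no shared code with write_envi()
  con <- file(paste0(stem, ".raw"), "wb")
  for (l in seq_len(3)) for (b in seq_len(4)) for (s in seq_len(5)) {
    writeBin(cube$data[l, s, b], con, size = 4L, endian = "little")
  }
  close(con)
  writeLines(c("ENVI", "samples = 5", "lines = 3", "bands = 4",
               "data type = 4", "interleave = bil", "byte order = 0",
               "range tag = SWIR", "calibrated = 1",
               paste0("wavelength = {",
                      paste(sprintf("%.3f", cube$wavelengths_nm), collapse = ", "),
                      "}")),
             paste0(stem, ".hdr"))
  back <- read_envi(paste0(stem, ".hdr"))
  expect_identical(back$data, cube$data)

  # and the package's own BSQ and BIL encodings agree after reading
  s1 <- file.path(withr::local_tempdir(), "a"); write_envi(cube, s1, "bsq")
  s2 <- file.path(withr::local_tempdir(), "b"); write_envi(cube, s2, "bil")
  expect_identical(read_envi(s1)$data, read_envi(s2)$data)
})

test_that("write -> read -> write produces byte-identical rasters", {
  cube <- f32_cube()
  dir <- withr::local_tempdir()
  write_envi(cube, file.path(dir, "one"))
  write_envi(read_envi(file.path(dir, "one.hdr")), file.path(dir, "two"))
  expect_identical(unname(tools::md5sum(file.path(dir, "one.raw"))),
                   unname(tools::md5sum(file.path(dir, "two.raw"))))
})

test_that("uint16 export round-trips integer counts", {
  cube <- hypercube(array(sample(0:65535, 64, replace = TRUE), c(2, 4, 8)),
                    seq(900, by = 100, length.out = 8), "SWIR")
  stem <- file.path(withr::local_tempdir(), "u16")
  write_envi(cube, stem, data_type = 12L)
  expect_equal(read_envi(stem)$data, cube$data)
  bad <- hypercube(array(runif(64), c(2, 4, 8)),
                   seq(900, by = 100, length.out = 8), "SWIR")
  expect_error(write_envi(bad, stem, data_type = 12L),
               class = "phenomap_error_parameter")
})

test_that("malformed headers and truncated rasters are rejected", {
  cube <- f32_cube()
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "cube")
  write_envi(cube, stem)

  hdr <- readLines(paste0(stem, ".hdr"))
  # wavelength count disagreeing with `bands`
  bad1 <- sub("^wavelength = \\{[^,]*, ", "wavelength = {", hdr)
  writeLines(bad1, file.path(dir, "bad1.hdr"))
  file.copy(paste0(stem, ".raw"), file.path(dir, "bad1.raw"))
  expect_error(read_envi(file.path(dir, "bad1.hdr")),
               class = "phenomap_error_format")
  # no wavelength block at all
  writeLines(hdr[!grepl("^wavelength =", hdr)], file.path(dir, "bad2.hdr"))
  file.copy(paste0(stem, ".raw"), file.path(dir, "bad2.raw"))
  expect_error(read_envi(file.path(dir, "bad2.hdr")),
               class = "phenomap_error_format")
  # raster shorter than the header promises
  writeLines(hdr, file.path(dir, "bad3.hdr"))
  raw <- readBin(paste0(stem, ".raw"), "raw", n = 100)
  writeBin(raw, file.path(dir, "bad3.raw"))
  expect_error(read_envi(file.path(dir, "bad3.hdr")),
               class = "phenomap_error_corrupt_file")
})

test_that("reflectance correction maps white to 1, dark to 0, midpoint to 0.5", {
  b <- 8L
  wl <- seq(1000, by = 50, length.out = b)
  white <- array(rep(seq(0.8, 0.95, length.out = b), each = 12), c(3, 4, b))
  dark <- array(rep(seq(0.04, 0.06, length.out = b), each = 12), c(3, 4, b))
  refs <- reference_frames(white, dark)
  as_cube <- function(a) hypercube(a, wl, "SWIR")
  expect_equal(calibrate_reflectance(as_cube(white), refs)$data,
               array(1, c(3, 4, b)))
  expect_equal(calibrate_reflectance(as_cube(dark), refs)$data,
               array(0, c(3, 4, b)))
  expect_equal(calibrate_reflectance(as_cube((white + dark) / 2), refs)$data,
               array(0.5, c(3, 4, b)))
})

test_that("reflectance is invariant to a common positive gain on all counts", {
  scene <- noiseless_scene()
  r1 <- calibrate_reflectance(scene$cube, scene$refs)
  gained <- hypercube(scene$cube$data * 3.7, scene$cube$wavelengths_nm, "SWIR")
  refs2 <- reference_frames(scene$refs$white * 3.7, scene$refs$dark * 3.7)
  r2 <- calibrate_reflectance(gained, refs2)
  expect_equal(r2$data, r1$data, tolerance = 1e-12)
})

test_that("coincident white/dark references are refused", {
  wl <- seq(1000, by = 50, length.out = 8)
  same <- array(0.5, c(2, 2, 8))
  expect_error(
    calibrate_reflectance(hypercube(array(0.4, c(2, 2, 8)), wl, "SWIR"),
                          reference_frames(same, same)),
    class = "phenomap_error_degenerate_reference"
  )
})

test_that("wavelength trimming keeps exactly the closed-interval bands", {
  wl <- seq(900, 2500, by = 10)
  cube <- hypercube(array(runif(4 * length(wl)), c(2, 2, length(wl))), wl, "SWIR")
  trimmed <- trim_wavelengths(cube, 920, 1970)
  expect_identical(dim(trimmed)[3], 106L)  # grid points in [920, 1970] at 10 nm
  expect_true(all(trimmed$wavelengths_nm >= 920 & trimmed$wavelengths_nm <= 1970))
  expect_identical(trim_wavelengths(cube, 900, 2500)$data, cube$data)
  expect_error(trim_wavelengths(cube, 2600, 2700),
               class = "phenomap_error_empty_range")
  expect_error(trim_wavelengths(cube, 1500, 1000),
               class = "phenomap_error_parameter")
})
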
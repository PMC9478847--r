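#' Partition a plant mask into random spatial regions
#'
#' Divides the canopy pixels into `k` regions so that per-region mean
#' spectra capture within-plant physiological variation. The default
#' labelling is seeded k-means on pixel coordinates, which yields
#' spatially coherent patches; `method = "random"` assigns pixels to
#' regions uniformly at random instead.
#'
#' @param mask A `plant_mask` (or logical matrix).
#' @param k Number of regions (canonically 10).
#' @param seed Integer seed.
#' @param method `"kmeans"` (contiguous patches) or `"random"`.
#' @return An integer H x W matrix: region label 1..k on canopy pixels,
#'   `NA` elsewhere.
#' @export
partition_regions <- function(mask, k = 10L, seed = 1L,
                              method = c("kmeans", "random")) {
  method <- match.arg(method)
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  k <- as.integer(k)
  if (k < 1L) abort_phenomap("`k` must be >= 1", "phenomap_error_parameter")
  px <- which(m, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    abort_phenomap("mask is empty", "phenomap_error_empty_mask")
  }
  if (nrow(px) < k) {
    abort_phenomap(
      sprintf("mask has %d pixels, fewer than k = %d regions", nrow(px), k),
      "phenomap_error_insufficient_pixels"
    )
  }
  labels <- with_seed(seed, {
    if (k == 1L) {
      rep(1L, nrow(px))
    } else if (method == "kmeans") {
      # a non-converged k-means is still a valid region partition
      suppressWarnings(
        stats::kmeans(px, centers = k, nstart = 5L, iter.max = 200L)$cluster
      )
    } else {
      # balanced random assignment: shuffle, deal into k hands
      lab <- rep_len(seq_len(k), nrow(px))
      lab[sample.int(nrow(px))] <- lab
      lab
    }
  })
  out <- matrix(NA_integer_, nrow(m), ncol(m))
  out[px] <- as.integer(labels)
  out
}

#' Mean spectra of labelled regions
#'
#' Computes the per-band arithmetic mean spectrum of every region in a
#' labelled canopy, returning one wide tibble row per region. Ten regions
#' per plant over a 120-plant cohort yields the canonical 1,200-spectrum
#' modelling table.
#'
#' @param cube A calibrated [hypercube()].
#' @param labelling Integer label matrix from [partition_regions()].
#' @param plant_id,condition Metadata recorded on every row.
#' @return A spectra table (tibble) with columns `plant_id`, `region_id`,
#'   `condition`, `y` (`NA` until [assign_reference()]), `split`, and one
#'   column per wavelength.
#' @export
extract_mean_spectra <- function(cube, labelling, plant_id = "plant_001",
                                 condition = "unlabelled") {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated) {
    abort_phenomap("spectra must be extracted from a calibrated cube",
                   "phenomap_error_state")
  }
  d <- dim(cube$data)
  if (!all(dim(labelling) == d[1:2])) {
    abort_phenomap("labelling shape does not match the cube",
                   "phenomap_error_format")
  }
  px <- which(!is.na(labelling))
  if (length(px) == 0L) {
    abort_phenomap("labelling has no labelled pixels", "phenomap_error_empty_mask")
  }
  labs <- labelling[px]
  pixmat <- matrix(cube$data, d[1L] * d[2L], d[3L])[px, , drop = FALSE]
  sums <- rowsum(pixmat, labs)
  counts <- as.vector(table(labs))
  means <- sums / counts
  region_ids <- as.integer(rownames(sums))
  meta <- tibble::tibble(
    plant_id = plant_id,
    region_id = region_ids,
    condition = condition,
    y = NA_real_,
    split = "unassigned"
  )
  rebuild_spectra_table(meta, means, cube$wavelengths_nm)
}

#' Read a phenolic compound reference table
#'
#' Reads a wide CSV of HPLC compound concentrations (mg/g DW): one row per
#' compound, one column per growing condition, with `"ND"` marking
#' compounds not detected. The packaged table
#' (`system.file("extdata", "phenolic_compounds.csv", package = "phenomap")`)
#' lists twelve phenylpropanoid compounds across eight light x drought
#' growing conditions.
#'
#' @param path CSV path; defaults to the packaged reference table.
#' @return A tibble: `compound` column plus one numeric-or-`"ND"` character
#'   column per condition.
#' @export
read_compound_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phenolic_compounds.csv", package = "phenomap")
  }
  tbl <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Total phenolic content per growing condition
#'
#' Sums the individual compound concentrations within each condition
#' column, treating `"ND"` (not detected) as zero, to give the total
#' phenolic content in mg/g dry weight that serves as the model's
#' reference value.
#'
#' @param table A compound table as returned by [read_compound_table()].
#' @return A tibble with columns `condition` and `total_phenolics_mg_per_g`.
#' @export
total_phenolics <- function(table) {
  cond_cols <- setdiff(names(table), "compound")
  totals <- vapply(cond_cols, function(cc) {
    v <- table[[cc]]
    num <- suppressWarnings(as.numeric(ifelse(trimws(v) == "ND", "0", v)))
    if (anyNA(num)) {
      abort_phenomap(sprintf("non-numeric entry in column '%s'", cc),
                     "phenomap_error_invalid_table")
    }
    if (any(num < 0)) {
      abort_phenomap(sprintf("negative concentration in column '%s'", cc),
                     "phenomap_error_invalid_table")
    }
    sum(num)
  }, numeric(1))
  tibble::tibble(condition = cond_cols, total_phenolics_mg_per_g = unname(totals))
}

#' Packaged reference totals
#'
#' Convenience wrapper: total phenolic content per condition from the
#' packaged compound table.
#'
#' @return A tibble with columns `condition` and `total_phenolics_mg_per_g`.
#' @export
phenolic_reference_totals <- function() {
  total_phenolics(read_compound_table())
}

#' Attach group-level reference values to a spectra table
#'
#' Sets `y` of every row to the total phenolic content of the row's
#' growing condition — the group-level assignment imposed by pooled
#' wet-chemistry references.
#'
#' @param table A spectra table.
#' @param totals A tibble with columns `condition` and
#'   `total_phenolics_mg_per_g` (e.g. from [total_phenolics()]).
#' @return The table with `y` filled in.
#' @export
assign_reference <- function(table, totals) {
  idx <- match(table$condition, totals$condition)
  if (anyNA(idx)) {
    missing <- unique(table$condition[is.na(idx)])
    abort_phenomap(
      paste0("conditions without reference totals: ", paste(missing, collapse = ", ")),
      "phenomap_error_lookup"
    )
  }
  table$y <- totals$total_phenolics_mg_per_g[idx]
  table
}

#' Split a spectra table into calibration and validation partitions
#'
#' Tags each row `"cal"` or `"val"`. At `level = "spectrum"` rows are
#' sampled independently (the classical 70:30 split of the 1,200-spectrum
#' table -> 840/360); at `level = "plant"` all regions of a plant share one
#' tag, which avoids leaking plant identity across partitions.
#'
#' @param table A spectra table.
#' @param ratio Calibration fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param level `"spectrum"` or `"plant"`.
#' @return The table with its `split` column assigned.
#' @export
split_calibration_validation <- function(table, ratio = 0.7, seed = 1L,
                                         level = c("spectrum", "plant")) {
  level <- match.arg(level)
  if (!(ratio > 0 && ratio < 1)) {
    abort_phenomap("`ratio` must be in (0, 1)", "phenomap_error_parameter")
  }
  n <- nrow(table)
  with_seed(seed, {
    if (level == "spectrum") {
      n_cal <- round(n * ratio)
      if (n_cal == 0L || n_cal == n) {
        abort_phenomap("split leaves an empty partition", "phenomap_error_split")
      }
      cal_rows <- sample.int(n, n_cal)
      table$split <- "val"
      table$split[cal_rows] <- "cal"
    } else {
      plants <- unique(table$plant_id)
      n_cal <- round(length(plants) * ratio)
      if (n_cal == 0L || n_cal == length(plants)) {
        abort_phenomap("split leaves an empty partition", "phenomap_error_split")
      }
      cal_plants <- sample(plants, n_cal)
      table$split <- ifelse(table$plant_id %in% cal_plants, "cal", "val")
    }
  })
  table
}

#' Build the modelling table for a synthetic cohort
#'
#' End-to-end extraction: for each plant in a cohort, render the scene,
#' calibrate reflectance, trim to the modelling window, segment the canopy
#' (falling back to the truth mask on request), partition it into `k`
#' regions and extract mean spectra; then attach group-level references.
#'
#' @param cohort Output of [generate_cohort()].
#' @param k Regions per plant.
#' @param trim Length-2 modelling window in nm (defaults per range tag:
#'   920-1,970 for SWIR, 400-990 for VIS/NIR).
#' @param use_truth_mask Use the generator's footprint instead of
#'   segmenting (faster; for ablation).
#' @param region_method Passed to [partition_regions()].
#' @param seed Integer seed for region partitions.
#' @return A spectra table with references assigned (split still
#'   `"unassigned"`).
#' @export
extract_cohort_spectra <- function(cohort, k = 10L, trim = NULL,
                                   use_truth_mask = FALSE,
                                   region_method = "kmeans", seed = 1L) {
  specs <- cohort$plants$spec
  rows <- purrr::map(seq_along(specs), function(i) {
    sp <- specs[[i]]
    scene <- generate_scene(sp)
    cube <- calibrate_reflectance(scene$cube, scene$refs)
    window <- trim %||% if (sp$range_tag == "SWIR") c(920, 1970) else c(400, 990)
    cube <- trim_wavelengths(cube, window[1L], window[2L])
    mask <- if (use_truth_mask) {
      structure(list(mask = scene$truth$mask,
                     source_wavelengths = numeric(0),
                     method_params = list(threshold_source = "truth")),
                class = "plant_mask")
    } else {
      segment_plant(cube)
    }
    labelling <- partition_regions(mask, k = k, seed = seed + i,
                                   method = region_method)
    extract_mean_spectra(cube, labelling,
                         plant_id = cohort$plants$plant_id[i],
                         condition = cohort$plants$condition[i])
  })
  table <- dplyr::bind_rows(rows)
  assign_reference(table, cohort$reference)
}
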
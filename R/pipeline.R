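#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end synthetic study into one validated
#' list: cohort design, scene geometry/noise, modelling window, split
#' policy, pretreatment set, latent-variable policy and band-selection
#' parameters. Defaults reproduce the canonical study design: 8 growing
#' conditions x 15 plants, SWIR cubes trimmed to 920-1,970 nm, 10 regions
#' per plant, a 70:30 spectrum-level split, and all eight pretreatments.
#'
#' @param range_tag `"SWIR"` or `"VISNIR"`.
#' @param n_conditions,plants_per_condition Cohort design.
#' @param image_size Scene height/width in px.
#' @param plant_radius Canopy radius in px (scale with `image_size`).
#' @param noise_sd,scatter_gain_sd,scatter_offset_sd Scene noise model.
#' @param plant_sd Within-condition SD of true totals (mg/g DW).
#' @param trim Modelling window (nm); default per range tag.
#' @param k_regions Regions per plant.
#' @param split_ratio,split_level Partition policy.
#' @param preprocess_methods Character vector of pretreatment names.
#' @param n_lv `"cv"` or a fixed integer.
#' @param max_lv CV search ceiling.
#' @param hf_cut,min_separation Band-selection parameters
#'   (`min_prominence` defaults to 5% of the score range).
#' @param map_preprocess Pretreatment used for the chemical-image stage.
#' @param compare_models Also fit SVM/tree/PCR comparators on the reduced
#'   sg2 dataset.
#' @param seed Master seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(range_tag = "SWIR",
                            n_conditions = 8L, plants_per_condition = 15L,
                            image_size = 64L, plant_radius = 18,
                            noise_sd = 0.01,
                            scatter_gain_sd = 0.05, scatter_offset_sd = 0.01,
                            plant_sd = 0.05,
                            trim = NULL, k_regions = 10L,
                            split_ratio = 0.7, split_level = "spectrum",
                            preprocess_methods = c("mean_norm", "max_norm",
                                                   "range_norm", "msc", "snv",
                                                   "sg1", "sg2", "raw"),
                            n_lv = "cv", max_lv = 15L,
                            hf_cut = 0.5, min_separation = 1L,
                            map_preprocess = "sg2",
                            compare_models = FALSE,
                            seed = 1L) {
  known <- c("raw", "mean_norm", "max_norm", "range_norm", "msc", "snv",
             "sg1", "sg2")
  bad <- setdiff(preprocess_methods, known)
  if (length(bad) > 0L) {
    abort_phenomap(paste0("unknown preprocessing method(s): ",
                          paste(bad, collapse = ", ")),
                   "phenomap_error_config")
  }
  if (!map_preprocess %in% preprocess_methods) {
    abort_phenomap("`map_preprocess` must be one of `preprocess_methods`",
                   "phenomap_error_config")
  }
  if (!split_level %in% c("spectrum", "plant")) {
    abort_phenomap("`split_level` must be 'spectrum' or 'plant'",
                   "phenomap_error_config")
  }
  structure(
    list(range_tag = range_tag, n_conditions = as.integer(n_conditions),
         plants_per_condition = as.integer(plants_per_condition),
         image_size = as.integer(image_size), plant_radius = plant_radius,
         noise_sd = noise_sd,
         scatter_gain_sd = scatter_gain_sd,
         scatter_offset_sd = scatter_offset_sd, plant_sd = plant_sd,
         trim = trim, k_regions = as.integer(k_regions),
         split_ratio = split_ratio, split_level = split_level,
         preprocess_methods = preprocess_methods,
         n_lv = n_lv, max_lv = as.integer(max_lv),
         hf_cut = hf_cut, min_separation = as.integer(min_separation),
         map_preprocess = map_preprocess,
         compare_models = isTRUE(compare_models),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic study end to end
#'
#' simulate -> calibrate -> segment -> extract -> split -> (for every
#' pretreatment) fit on the full wavebands, select wavebands on the
#' calibration rows, refit on the reduced set -> map one plant. Returns a
#' run manifest holding the configuration echo, the metrics table (one row
#' per pretreatment x band set), the per-pretreatment selections and the
#' chemical-image summary. With an `out_dir`, artifacts (model JSONs,
#' selection JSONs, metrics CSV, rendered map) are written and their MD5
#' hashes recorded in the manifest.
#'
#' Identical configuration and seed reproduce the manifest exactly: every
#' random draw derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @return A `pipeline_manifest` list: `config`, `n_spectra`, `n_cal`,
#'   `n_val`, `metrics` (tibble), `selections`, `map_summary`,
#'   `comparators` (if requested), `hashes` (if written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(
    n_conditions = config$n_conditions,
    plants_per_condition = config$plants_per_condition,
    plant_sd = config$plant_sd, seed = config$seed,
    range_tag = config$range_tag,
    image_height = config$image_size, image_width = config$image_size,
    plant_radius = config$plant_radius,
    noise_sd = config$noise_sd,
    scatter_gain_sd = config$scatter_gain_sd,
    scatter_offset_sd = config$scatter_offset_sd
  )
  table <- extract_cohort_spectra(cohort, k = config$k_regions,
                                  trim = config$trim, seed = config$seed)
  table <- split_calibration_validation(table, ratio = config$split_ratio,
                                        seed = config$seed,
                                        level = config$split_level)
  models <- list()
  selections <- list()
  metric_rows <- list()
  for (meth in config$preprocess_methods) {
    spec <- preprocess_spec(meth)
    full <- fit_phenolics_model(table, preprocess = spec, n_lv = config$n_lv,
                                max_lv = config$max_lv, seed = config$seed)
    sel <- select_wavebands(table, preprocess = preprocess_spec(meth),
                            hf_cut = config$hf_cut,
                            min_separation = config$min_separation)
    reduced <- if (length(sel$selected_indices) > 0L) {
      fit_phenolics_model(table, preprocess = preprocess_spec(meth),
                          selection = sel, n_lv = config$n_lv,
                          max_lv = min(config$max_lv,
                                       length(sel$selected_indices)),
                          seed = config$seed)
    } else {
      NULL
    }
    models[[meth]] <- list(full = full, reduced = reduced)
    selections[[meth]] <- sel
    metric_rows[[meth]] <- dplyr::bind_rows(
      dplyr::mutate(glance(full), band_set = "full", .before = 1L),
      if (!is.null(reduced)) {
        dplyr::mutate(glance(reduced), band_set = "reduced", .before = 1L)
      }
    )
  }
  metrics <- dplyr::bind_rows(metric_rows)

  # chemical image of the first plant under the mapping pretreatment
  map_model <- models[[config$map_preprocess]]$full
  sp <- cohort$plants$spec[[1L]]
  scene <- generate_scene(sp)
  cube <- calibrate_reflectance(scene$cube, scene$refs)
  window <- config$trim %||% if (sp$range_tag == "SWIR") c(920, 1970) else c(400, 990)
  cube <- trim_wavelengths(cube, window[1L], window[2L])
  mask <- segment_plant(cube)
  chem <- apply_model_to_cube(cube, mask, map_model)
  map_summary <- dplyr::mutate(plant_prediction(chem),
                               plant_id = cohort$plants$plant_id[1L],
                               true_concentration = cohort$plants$true_concentration[1L],
                               .before = 1L)

  comparators <- NULL
  if (config$compare_models) {
    sel_sg2 <- selections[["sg2"]] %||% selections[[config$map_preprocess]]
    comparators <- dplyr::bind_rows(
      lapply(c("svm", "regression_tree", "pcr"), function(mm) {
        fit_comparator(table, mm, preprocess = preprocess_spec("sg2"),
                       selection = sel_sg2)
      })
    )
  }

  manifest <- structure(
    list(config = unclass(config),
         n_spectra = nrow(table),
         n_cal = sum(table$split == "cal"),
         n_val = sum(table$split == "val"),
         metrics = metrics,
         selections = lapply(selections, function(s) {
           list(selected_indices = s$selected_indices,
                wavelengths_nm = s$wavelengths_nm)
         }),
         map_summary = map_summary,
         comparators = comparators),
    class = "pipeline_manifest"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    for (meth in names(models)) {
      write_model(models[[meth]]$full,
                  file.path(out_dir, paste0("model_", meth, "_full.json")))
      if (!is.null(models[[meth]]$reduced)) {
        write_model(models[[meth]]$reduced,
                    file.path(out_dir, paste0("model_", meth, "_reduced.json")))
      }
      write_band_selection(selections[[meth]],
                           file.path(out_dir, paste0("selection_", meth, ".json")))
    }
    render_map(chem, file.path(out_dir, "chemical_map.png"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$hashes <- stats::setNames(as.vector(tools::md5sum(files)),
                                       basename(files))
    jsonlite::write_json(
      manifest[setdiff(names(manifest), "hashes")],
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
  }
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> %d spectra (%d cal / %d val)\n",
              x$n_spectra, x$n_cal, x$n_val))
  print(x$metrics[, c("band_set", "preprocess", "n_bands", "n_lv",
                      "r2_cal", "sec", "r2_val", "sep")])
  invisible(x)
}
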
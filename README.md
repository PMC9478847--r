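# phenomap

Non-destructive estimation of **total phenolic content** (mg/g dry weight)
in rosette plants from hyperspectral reflectance imagery, with per-pixel
chemical concentration maps.

Phenolic compounds are a major class of plant secondary metabolites whose
accumulation responds strongly to light quality and drought stress. The
reference assay (HPLC of pooled tissue) is destructive and slow; imaging
spectroscopy offers a rapid alternative: phenolic CH-overtone absorption
features near 1,110–1,130 nm and 1,645–1,670 nm (SWIR), and 450–475 /
535–565 nm (VIS/NIR), modulate canopy reflectance in proportion to
concentration. `phenomap` implements the full chemometrics workflow for
exploiting this, and ships a synthetic scene generator with known ground
truth so the whole pipeline can be validated end to end.

## The pipeline

1. **Reflectance calibration.** Raw counts are corrected with white/dark
   references: `I_c = (I_h − I_d) / (I_w − I_d)`.
2. **Canopy segmentation.** Band composites at 947/1,535/1,946 nm (SWIR)
   or 560/655/750 nm (VIS/NIR), a normalized-difference score, Otsu
   thresholding, largest-component keep and hole fill.
3. **Spectral dataset.** Each canopy is divided into 10 random spatial
   regions (seeded k-means on pixel coordinates); region mean spectra form
   the modelling table (120 plants × 10 regions = 1,200 spectra), each row
   tagged with its growing condition's group-level HPLC total. A 70:30
   split separates calibration and validation.
4. **Pretreatment.** Eight row-wise options: raw, mean/max/range
   normalization, MSC, SNV, Savitzky–Golay 1st/2nd derivatives.
5. **PLSR (NIPALS).** `X = A Bᵀ + C`, `Y = D Eᵀ + F`, inner relation
   `D = A G + H` with `G = (AᵀA)⁻¹AᵀD`; the latent-variable count is
   chosen by one-SE cross-validation; performance is reported as
   R²c/SEC and R²v/SEP.
6. **DCT waveband reduction.** For each band, the across-sample vector is
   cosine-transformed; the DC coefficient and the high-frequency half of
   the AC coefficients are discarded and the band is scored by its largest
   remaining |AC| coefficient. Peaks of the score profile are the selected
   wavebands, and the model is refitted on them.
7. **Chemical imaging.** The regression vector `K` is applied at every
   canopy pixel, `I_ch = Σᵢ Iᵢ Kᵢ L` (plus the model's centering and
   intercept so units stay mg/g DW), giving a blue-to-red concentration
   map and a per-plant mean prediction.

The packaged HPLC reference table
(`inst/extdata/phenolic_compounds.csv`) lists twelve phenylpropanoid
compounds across eight light × drought growing conditions; its
per-condition totals (0.977–2.194 mg/g DW) anchor both the reference
values and the synthetic cohort's dynamic range.

## Worked example

A desk-scale synthetic study (8 conditions × 2 plants, 32 px SWIR scenes)
runs in a few seconds:

```r
library(phenomap)

cohort  <- generate_cohort(plants_per_condition = 2, seed = 42,
                           image_height = 32, image_width = 32, plant_radius = 9)
spectra <- extract_cohort_spectra(cohort, seed = 42) |>
  split_calibration_validation(ratio = 0.7, seed = 42)

model <- fit_phenolics_model(spectra, preprocess_spec("sg2"), n_lv = "cv", seed = 42)
glance(model)
#> # A tibble: 1 × 9
#>   preprocess n_bands  n_lv r2_cal    sec r2_val    sep rmse_val bias_val
#>   <chr>        <int> <int>  <dbl>  <dbl>  <dbl>  <dbl>    <dbl>    <dbl>
#> 1 sg2            106     3  0.973 0.0613  0.931 0.0872   0.0879   0.0172

sel <- select_wavebands(spectra, preprocess_spec("sg2"))
round(sel$wavelengths_nm)
#>  [1]  920 1070 1120 1170 1370 1450 1530 1600 1650 1700 1970

reduced <- fit_phenolics_model(spectra, preprocess_spec("sg2"),
                               selection = sel, n_lv = "cv", seed = 42)
glance(reduced)
#> # A tibble: 1 × 9
#>   preprocess n_bands  n_lv r2_cal    sec r2_val    sep rmse_val bias_val
#>   <chr>        <int> <int>  <dbl>  <dbl>  <dbl>  <dbl>    <dbl>    <dbl>
#> 1 sg2             11     2  0.959 0.0750  0.929 0.0895   0.0896   0.0137
```

Reading the output: the second-derivative model explains 93% of
validation variance with a standard error of prediction of 0.087 mg/g
over references spanning 0.98–2.19 mg/g; waveband reduction keeps 11 of
106 bands — including 1,120 nm and 1,650 nm, inside the two phenolic
CH-overtone windows — at essentially unchanged accuracy. `autoplot()` on
the model, a band selection or a chemical image draws the standard
diagnostic figures, and `run_pipeline(pipeline_config(...))` orchestrates
the whole study (all eight pretreatments × full/reduced wavebands) into a
reproducible manifest. A thin command-line wrapper for the individual
steps lives at `inst/scripts/phenomap.R`.

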
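---
title: "Methods: hyperspectral prediction and mapping of total phenolic content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral prediction and mapping of total phenolic content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

## The problem and the measurement model

Total phenolic content — the summed concentration of individually
quantified phenolic compounds, in mg per g dry weight (DW) — is a
standard quality and stress marker in plants. The wet-chemistry reference
(HPLC of pooled, powdered tissue) destroys the sample and, for small
rosette plants, requires pooling a whole growing-condition group to reach
the minimum tissue mass. Imaging spectroscopy offers a non-destructive
route: phenolic C–H bonds produce overtone absorption in two SWIR windows
(second overtone near 1,110–1,130 nm, first overtone near 1,645–1,670 nm)
and electronic absorption in the visible (450–475 and 535–565 nm), so
canopy reflectance carries a concentration signal that a multivariate
calibration can extract.

`phenomap` implements that calibration chain end to end. Because the kind
of imagery involved is rarely public, the package treats a *synthetic
scene generator with known ground truth* as a first-class component: every
stage of the pipeline is validated against quantities the generator
controls exactly.

## The synthetic scene generator

A scene is one potted rosette plant viewed from above. Its ingredients:

* **Endmembers** (`generate_basis_spectra()`): a smooth vegetation
  baseline (chlorophyll edge in VIS/NIR; water absorption near 1,450 and
  1,940 nm in SWIR), soil and pot background spectra, white/dark
  reference levels, and a non-negative phenolic absorption signature
  expressed per mg/g DW, built from Gaussian bands centred inside the
  windows above (SWIR amplitudes 0.030 and 0.024 reflectance per mg/g,
  widths 12 and 14 nm). Small seeded jitters of amplitudes and centres
  emulate plant-to-plant biological variability.
* **Geometry**: the canopy is a rosette of overlapping disks (six leaves
  around a central disk by default) rather than a single disk, so that
  random region partitions are spatially non-trivial; the painted
  footprint is retained as the truth mask.
* **Optics**: the latent reflectance of a canopy pixel is
  `a · (vegetation − c · signature) + b` with per-pixel
  `a ~ N(1, 0.05)` and `b ~ N(0, 0.01)`. This affine gain/offset is
  exactly the distortion family MSC and SNV are designed to remove, which
  makes pretreatment comparisons meaningful rather than decorative.
  Raw counts are `dark + latent · (white − dark)` plus `N(0, 0.01)`
  sensor noise; reference frames carry the same noise level. With all
  noise terms at zero the calibration equation inverts the construction
  exactly, which the tests exploit as a machine-precision round trip.
* **Cohort design** (`generate_cohort()`): eight growing conditions ×
  15 plants. Condition mean totals default to the packaged HPLC table's
  totals (0.977–2.194 mg/g DW), tying the synthetic dynamic range to real
  reference chemistry. Per-plant true totals are drawn from
  `N(condition mean, plant_sd)`; the reference table exposed to the
  modelling code stores only the condition mean, mirroring pooled
  group-level HPLC, while per-plant truth is kept separately for recovery
  tests.

**Choice of `plant_sd`.** Within-condition variability of per-plant totals
is not something a pooled assay can report; the generator therefore
exposes it as a parameter. The default of 0.05 mg/g was chosen once as
realistic — the packaged table's group SDs run 0.013–0.241 mg/g with a
median near 0.04 — and doubles as an honest noise floor: group-level
references can never be recovered per plant below this dispersion.

**What the generator does not emulate**: radiative-transfer leaf optics
(no PROSPECT-style scattering physics), line-scan geometric distortion,
soil/pot texture, specular highlights, or overlapping neighbour plants.
Passing tests therefore demonstrate that the *chain of algorithms* is
correct and self-consistent under a plausible optical model — not that the
specific accuracy figures transfer to any particular instrument or
species.

## Stage-by-stage choices

**Calibration.** White/dark frames are averaged across acquisition lines
before the two-point correction (suppresses shot noise; per-line
references remain possible by passing single-line frames). Reflectance is
clipped to [0, 1.5] and the clipped-voxel count is recorded, since
out-of-range values are otherwise silent. Grids are trimmed to the
low-noise sensor windows: 400–990 nm (VIS/NIR), 920–1,970 nm (SWIR).

**Segmentation.** The wavelengths of the segmentation composites are
fixed (947/1,535/1,946 nm SWIR; 560/655/750 nm VIS/NIR) but the
classifier behind them was an open choice. The package uses a
normalized-difference score between the vegetation-bright and
water-absorption channels, Otsu's threshold, largest connected component
and hole filling — parameter-light, fully auditable (every parameter lands
in `method_params`), and overridable with a manual threshold. On default
synthetic scenes this recovers the truth footprint with IoU ≥ 0.95, and
accuracy degrades monotonically with sensor noise.

**Region partition.** "Divide the canopy into ten random regions" admits
many readings; the default is seeded k-means on pixel coordinates, giving
contiguous patches that behave like physiological sub-regions of a leaf
rosette. A uniform random assignment is available behind a flag for
comparison. Region means conserve the whole-canopy mean exactly
(pixel-count weighting), which the tests assert to 1e-12.

**Split policy.** The canonical 70:30 split is drawn at the spectrum
level, which is what yields 840/360 from 1,200 rows. Note the caveat:
region spectra of one plant are highly correlated, so a spectrum-level
split leaks plant identity across partitions and flatters validation
metrics. A plant-level split (all ten regions share one tag) is provided
and recommended when honest generalization estimates matter; the
pipeline default follows the canonical design, not the cautious one, and
says so here deliberately.

**Pretreatments.** All eight transforms are row-local. MSC's reference is
the only fitted state; it is frozen from calibration rows and applied
unchanged to validation rows and map pixels (never a batch's own mean —
the tests assert this separation). Savitzky–Golay windows default to 11
points with polynomial order 2 (first derivative) and 3 (second);
derivatives are per band index, since trimmed grids are uniform and PLSR
is scale-equivariant; the wavelength spacing is recorded rather than
applied. Edge samples use the polynomial-fit extension rather than zero
padding.

**PLSR.** NIPALS was chosen over SIMPLS because the score/loading
decomposition (`X = A Bᵀ + C`, `Y = D Eᵀ + F`, `D = A G + H`) is the form
in which the model is usually stated, and keeping the stored matrices in
that form makes the implementation auditable against it. X is centered
but not variance-scaled — scaling is the pretreatment's job. The
latent-variable count is not a fixed constant of the method; the package
selects it by 5-fold cross-validation with the one-SE rule (smallest
count within one standard error of the minimum CV RMSE), seeded and
deterministic, and flags the choice in its outputs. SEC uses the
degrees-of-freedom convention `sqrt(RSS/(n − n_lv − 1))`; SEP is the
bias-corrected standard error of validation residuals, with plain RMSE
and bias reported alongside since usage of these terms varies.

**Waveband reduction.** The scoring statistic transforms, for each band,
the vector of that band's values *across calibration samples* (the
across-sample axis is the only reading in which each waveband owns its
own coefficient set; the per-spectrum alternative is implemented behind
`axis = "bands"` for comparison). The DC coefficient is excluded — it
carries only the band's mean level — and the upper half of the AC
frequencies (`hf_cut = 0.5`) is discarded as edge-like structure before
taking the maximum absolute retained coefficient. Because rows enter in
cohort order, condition structure is low-frequency along the sample axis
and survives the cut; the scores are order-sensitive, so the row order is
part of any serialized selection. Peak picking uses prominence ≥ 5% of
the score range and a minimum separation of one band, endpoints eligible,
plateaus represented by their left-most index, the higher peak winning a
separation conflict. All three parameters are configuration, not claims
about any external dataset. On planted cohorts the selection includes
bands inside both CH-overtone windows in ≥ 90% of seeded runs.

**Chemical imaging.** The per-band summation `I_ch = Σ Iᵢ Kᵢ L` is
applied per canopy pixel *after* the model's own pretreatment chain
(frozen MSC reference, same SG window) — applying regression coefficients
to spectra pretreated differently from the training data would evaluate
the model off its manifold. The model's centering and intercept are
included so map units remain mg/g DW; the display constant `L` defaults
to 1 and is never serialized into predictions. For linear chains (raw, SG
derivatives) the mask-mean of the map equals the prediction of the
mask-mean spectrum to 1e-8 by linearity; for row-nonlinear chains (SNV,
MSC, range normalization) no such identity holds and none is asserted.
Pixels whose pretreatment is undefined (e.g. SNV of a constant spectrum)
are flagged, counted and left as sentinels.

## Numerical and degenerate-input policy

Zero-variance responses, constant spectra under scale-dependent
transforms, coincident white/dark references, empty masks, empty
wavelength windows, rank-deficient predictor matrices and empty band
selections all raise classed errors (`phenomap_error_*`) rather than
propagating NaNs. Nearest-band lookup breaks ties toward the lower
wavelength. The orthonormal DCT satisfies Parseval to 1e-10 and is checked
against a direct O(n²) cosine sum. ENVI I/O uses a minimal dialect
(float32/uint16, little-endian, bsq/bil/bip) and round-trips rasters
byte-identically.

## Problem sizes used in the tests

The validation suite runs the full study design — 120 plants, 64 × 64 px
SWIR scenes, 161 bands trimmed to 106 — for the dataset-shape and
parameter-recovery checks (five seeded cohorts; validation R² ≥ 0.9 and
SEP ≤ 0.15 mg/g are the acceptance floors, with observed values around
0.97 and 0.06), and desk-scale cohorts (8 conditions × 2 plants, 32 px
scenes) for module-level properties and the 20-run band-selection
frequency check. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

## Known limitations

* Group-level references bound per-plant accuracy: the model is trained
  on condition means, so per-plant recovery inherits `plant_sd` as a
  floor.
* The spectrum-level default split overstates generalization (see above).
* The waveband-reduction statistic depends on sample order and on two
  cut parameters with no canonical values; selections should be compared
  only under identical configuration.
* Segmentation assumes one plant per scene (largest component wins) and
  no multi-plant instance separation.
* The generator's optical model is phenomenological; absolute metric
  values on synthetic scenes do not transfer to real instruments.
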
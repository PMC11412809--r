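---
title: "Methods: synthetic canopies, multiscale texture and LAI models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic canopies, multiscale texture and LAI models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopylai)
```

`canopylai` is a desk-scale analogue of a rice leaf-area-index (LAI)
remote-sensing study: it simulates a fertilizer trial imaged by an RGB
camera (1 cm ground resolution, digital numbers) and a 12-band
multispectral camera (8 cm, reflectance) at three growth stages, then
estimates LAI from spectral indices and multiscale image texture. This
vignette documents the model, every default, and the numerical
conventions, so that results can be interpreted and reproduced without
reading the source.

## 1. The synthetic canopy model

### Scene geometry

`build_layout()` places 72 plots of 4 m x 8 m on the squarest possible
grid (12 x 6 for 72), separated by 48 cm strips of dark film
(reflectance 0.02), as in transplanted paddy trials where plots are
isolated by plastic film. Crop rows run along the image columns; the
direction *perpendicular* to the rows is the image row axis.

### Ground truth

Each plot carries one of ten fertilizer treatments `T1..T10`
(multipliers 0.65-1.25 of the stage mean) and one of two varieties.
`sample_lai()` draws per-plot LAI from a zero-truncated normal around
the treatment-scaled stage mean (jointing 1.5, booting 3.5, heading 5.5;
sd 0.3). Stage means must increase, mirroring a crop approaching peak
canopy.

### Radiometry

Local canopy cover follows the Beer law. Within a plot, the local LAI
is modulated across the rows by a raised cosine,

$$\mathrm{LAI}_{loc}(y) = L \left(1 + 0.8 \cos\frac{2\pi y}{30\,\mathrm{cm}}\right),$$

with a 30 cm row spacing, and the gap fraction is
$P = e^{-k\,\mathrm{LAI}_{loc}}$ with extinction coefficient $k = 0.6$,
a standard mid-range value for rice canopies with mixed leaf angles.
Pixel reflectance mixes soil and leaf linearly:
$\rho = P\,\rho_{soil} + (1-P)\,\rho_{leaf}$. Leaf spectra follow a
piecewise-linear green-vegetation curve (chlorophyll troughs in blue and
at 670-680 nm, green bump, red edge, NIR plateau ~0.5); soil is flat at
0.20. Gaussian noise (sd 0.01) is added, values are clipped to [0, 1],
and the RGB sensor is scaled to digital numbers 0-255.

### What makes the generator realistic (and why)

Two effects beyond clean Beer-law mixing are deliberate defaults,
because they produce the *qualitative* behaviour the analysis is built
to handle:

* **Per-plot leaf/soil optical factors** (`leaf_vis_sd = 0.15`,
  `leaf_nir_sd = 0.06`, `soil_sd = 0.05`, lognormal, drawn per plot and
  stage). Fertilization changes leaf chlorophyll and structure, not just
  leaf area. Once the canopy closes ($P \to 0$) a pixel sees only leaf,
  so its reflectance varies with leaf quality rather than with LAI —
  this is precisely why spectral indices saturate and why texture
  (which responds to canopy surface structure) retains information.
* **Stage leaf factors** (`stage_leaf_vis` = 0.95 / 1.00 / 1.45 and
  `stage_leaf_nir` = 1.03 / 1.00 / 0.90 for jointing / booting /
  heading). At heading, emerged panicles — bright in the visible — overlay
  the canopy and the lowest leaves begin to senesce, raising effective
  visible reflectance and lowering NIR relative to booting. Vegetation
  indices therefore plateau or fall between booting and heading even
  though LAI keeps rising, so index-LAI curves shift between stages and
  *pooled* multi-stage correlations fall below single-stage ones.

With noise and these factors disabled, plot-mean NDVI is strictly
increasing and concave in LAI over [0.5, 7], and the 680 nm GLCM
homogeneity increases monotonically with LAI — the generator's sanity
anchors, covered by tests.

The generator does **not** emulate: view/illumination geometry (BRDF),
wind-blown row misalignment, georeferencing error, mixed pixels at plot
borders beyond the film strips, or sensor vignetting.

## 2. Raster handling and multiscale resampling

`lai_raster` is a minimal in-memory raster (rows x cols x bands array,
band labels, resolution in cm, value kind). `write_raster()` stores a
multi-page TIFF plus a JSON sidecar; reflectance and derived values are
packed losslessly (the 8 bytes of each float64 stored as four 16-bit
samples), so write/read round trips are bit-exact — a prerequisite for
the end-to-end determinism guarantee.

Coarsening uses nearest-neighbour resampling with the pixel-centre
convention: output pixel $d$ (0-based) takes source pixel
$\lfloor (d + 0.5)\,t/n \rfloor$ for target resolution $t$ and native
$n$; the output shape is $\lfloor \mathrm{extent}/t \rfloor$. Every
output value therefore occurs in the input (no interpolation), and
resampling at native resolution is the identity. Ladders are always
built directly from the native raster, never chained through
intermediate scales, to avoid compounding selection bias. The ladders
are 1/4/8/16/24/32/40/48 cm (RGB) and 8-48 cm (multispectral).

`roi_at_scale()` carries a plot window to a coarser grid by keeping the
coarse pixels whose nearest-neighbour source falls inside the native
window, then shrinking one coarse pixel per side to drop mixed border
pixels.

## 3. Spectral indices

Twelve RGB features (band digital numbers `R, G, B`; chromatic
coordinates `r, g, b` with $r = R/(R{+}G{+}B)$ etc.; `ExR`, `ExG`,
`ExB`, `ExG_ExR`, `VARI`, `GRVI`) and twenty multispectral features (the
twelve band reflectances 490-950 nm plus `NDVI`, `NDRE`, `EVI2`,
`GNDVI`, `CI_rededge`, `CI_green`, `VARI`, `OSAVI`). The two VARI
definitions differ, hence the sensor-qualified keys `VARI_rgb` /
`VARI_mca`. Division by zero yields `NaN` with a warning; `NaN` records
are excluded pairwise downstream.

Per-plot values average the band values over the plot window first and
evaluate the index on the means (`mode = "plot_mean"`), matching
plot-level reflectance extraction practice; per-pixel evaluation with
averaging afterwards is available as `mode = "pixel_mean"`.

## 4. GLCM texture

`quantize()` stretches a band linearly between its own minimum and
maximum onto 32 gray levels (per plot window for feature tables; once
globally per band for sliding-window maps, so neighbouring windows are
comparable). `glcm()` counts co-occurring level pairs at displacement
(1, 0) — one pixel perpendicular to the crop rows, the offset that sees
the row stripes — symmetrically, and normalizes. Eight statistics are
derived (mean, variance, homogeneity, contrast, dissimilarity, entropy,
second moment, correlation), with correlation defined as 1 for a
degenerate (zero-variance) matrix such as a constant window.

Normalized-difference textures $\mathrm{NDT}(t_1, t_2) =
(t_1 - t_2)/(t_1 + t_2)$ combine the 8 statistics into 28 ordered pairs.
Feature names encode statistic and scale: raw `Hom40`, `Mea8`;
normalized `meacor48`. The per-plot table holds 36 features per scale.
`sliding_texture()` computes the same statistics in a centred 9 x 9
window around every pixel, replicating edge pixels so the output keeps
the input's shape.

## 5. Screening, models and maps

`correlate()` reports Pearson r of every feature against LAI, per stage
or pooled ("multi"). `split_2to1()` assigns whole plots 2:1 to
calibration and validation (48/24 of 72), so the three stage records of
a plot never straddle the split.

`fit_msr()` is bidirectional p-value stepwise least squares
(entry p < 0.05, removal p > 0.10, lexicographic tie-break, collinear
terms treated as p = 1), reproducing the "multiple stepwise regression"
of agronomic practice rather than AIC-based `step()`. `fit_rf()` wraps
a seeded random forest (500 trees, `ceiling(m/3)` candidates per split).
`evaluate_model()` reports $R^2 = 1 - SS_{res}/SS_{tot}$, RMSE and MAE.

Fitted or printed models are `lai_equation` objects with a strict
round-trippable text form (`LAI=2.2-3.2*meacor48+18.68*R900`).
`parse_equation()` accepts the looser printed notation (optional `*`,
coefficient abutting the feature, bare intercept terms, lowercase raw
texture codes); `inst/extdata/equations.json` ships the printed model
library. `predict_map()` evaluates an equation per pixel, building each
texture term by sliding-window GLCM on the nearest-neighbour-coarsened
band and aligning all terms to the coarsest term resolution.

One subtlety matters when a fitted model is used for mapping: plot-table
textures (`plot_texture_table()`) stretch gray levels within each plot
window, while sliding textures stretch once globally, so the two feature
definitions are on different scales and coefficients fitted on the
former extrapolate badly on the latter. The pipeline therefore refits
its mapping model on *plot means of the sliding-window statistics* at
the map scale (`sliding_plot_features()`), which shares quantization and
window definition with the per-pixel predictor.

## 6. The pipeline and determinism

`run_all(run_config(out_dir, seed))` chains generate, extract, screen,
fit and map, writes CSV/TIFF/JSON artifacts, and ends with a manifest of
relative paths and MD5 hashes. All randomness derives from the one seed
through `derive_seed()` (scene draw, plot split, forest), and no
artifact contains timestamps, so two runs with the same configuration
produce byte-identical manifests. A full default run (both sensors, 72
plots, all scales) takes on the order of 3 minutes on one CPU.

## 7. Problem sizes

Default scenes are 5424 x 5136 cm: 5424 x 5136 px RGB and 678 x 642 px
multispectral. Feature tables hold 216 records (72 plots x 3 stages)
with 12 or 20 spectral features and 288 (8 scales) or 216 (6 scales)
texture features. Pixel-wise maps are produced at 48 cm (113 x 107 px)
by default to keep sliding-window GLCM tractable.
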
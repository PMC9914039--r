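# cbctiq — task-based image quality assessment for cone-beam CT

Iterative reconstruction (IR) algorithms for CT and cone-beam CT (CBCT) are
nonlinear: their spatial resolution depends on object contrast and noise
level, so classical metrics (pixel SD, MTF from a wire) can mislead when
comparing IR against filtered back projection (FBP). `cbctiq` implements the
three task-based metrics that medical physicists use instead, plus a
synthetic Catphan-like phantom generator so the whole pipeline can be
exercised and validated without acquisition data. It is aimed at medical
physicists and imaging researchers evaluating reconstruction algorithms or
acquisition protocols on axial CT/CBCT slice stacks in Hounsfield units.

## The metrics

**Noise power spectrum (2D NPS).** From square ROIs placed in a uniform
phantom module, with a second-order polynomial detrend per ROI:

```
NPS(fx, fy) = (Δx Δy) / (Lx Ly) · (1/N) Σᵢ |FFT₂D(ROIᵢ − FITᵢ)|²
```

The noise magnitude is `√(∬ NPS dfx dfy)` (equal to the detrended pixel SD
by Parseval's relation) and the noise texture is summarised by the radial
peak frequency `f_peak` (mm⁻¹).

**Task-based transfer function (TTF).** The circular-edge method on a
cylindrical contrast insert: each pixel's exact radius from the sub-pixel
insert centre builds an oversampled edge spread function, its derivative is
the line spread function, and the TTF is the normalised modulus of the LSF
Fourier transform. `f50`, the frequency where TTF = 0.5, summarises spatial
resolution for that contrast/noise condition. Insert contrast is measured
against a background annulus.

**NPWE detectability index.** The non-prewhitening model observer with eye
filter combines the two, for a circular lesion task `W` (analytic flat-disk
transform) under display/viewing geometry:

```
d′² = [∬ W² TTF² E² du dv]² / ∬ W² TTF² NPS E⁴ du dv
```

## Worked example

Generate a synthetic head-mode phantom pair and measure it back:

```r
library(cbctiq)

# uniformity module with an FBP-like band-pass noise texture
cfg <- phantom_config(matrix_size = 256, pixel_spacing_mm = 281.6/512,
                      n_slices = 20, noise_model = noise_model("fbp", 40, 0.29),
                      seed = 42)
uniform <- generate_uniform_module(cfg)
nps <- compute_nps(uniform, nps_roi_layout(uniform, side_px = 82,
                                           radial_offset_mm = 30))
nps
#> <nps_result> noise magnitude 40.05 HU over 80 ROI-slices
#>   radial profile: 42 bins to 0.909 /mm; peak(s): 0.29

# sensitometry module: four inserts, Gaussian system blur
icfg <- phantom_config(matrix_size = 256, pixel_spacing_mm = 281.6/512,
                       n_slices = 20,
                       insert_specs = default_inserts(circle_radius_mm = 40),
                       psf_sigma_mm = 0.47,
                       noise_model = noise_model("fbp", 40, 0.29), seed = 43)
inserts <- generate_insert_module(icfg)
gt <- inserts$meta$ground_truth$inserts
teflon <- insert_spec("teflon", c(gt$center_row_px[4], gt$center_col_px[4]))
ttf <- compute_ttf(inserts, teflon)
ttf
#> <ttf_result> insert 'teflon': contrast 791.0 HU, f50 0.418 /mm (20 slices)

compute_dprime(ttf, nps, task_spec(10, ttf$contrast_hu), viewing_conditions())
#> <detectability_result> d' = 99.33 (lesion 10.0 mm, contrast 791 HU)
```

The NPS recovers the prescribed 40 HU magnitude and 0.29 mm⁻¹ peak; the
measured `f50` of 0.418 mm⁻¹ reflects the 0.47 mm Gaussian PSF (closed form
0.399 mm⁻¹, here slightly higher because only 20 noisy slices are pooled);
d′ is the detectability of a 10 mm lesion at the Teflon contrast under the
default viewing conditions (500 mm distance, zoom 1.5, 0.2 mm pixel pitch).

`run_assessment()` orchestrates the full mode × reconstruction comparison
and emits summary tables with IR-vs-FBP percent changes; `exec/cbctiq`
exposes `simulate` / `nps` / `ttf` / `assess` subcommands for shell use.
Stacks are read and written as DICOM series or a simple headered raw format
(`read_stack()` / `write_stack()`).

## Vignette

`vignettes/task-based-cbct-iq.Rmd` documents the models, the synthetic
phantom's assumptions, all numerical design choices and known limitations.
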
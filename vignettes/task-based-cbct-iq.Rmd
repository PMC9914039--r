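---
title: "Task-based CBCT image quality: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CBCT image quality: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbctiq)
```

## Why task-based metrics

Iterative reconstruction (IR) is nonlinear: resolution depends on local
contrast and noise, and noise texture changes with the algorithm. Comparing
an IR and an FBP reconstruction therefore requires metrics measured under
the conditions of a concrete imaging task. `cbctiq` implements the standard
trio — 2D noise power spectrum (NPS), circular-edge task-based transfer
function (TTF) and the non-prewhitening-with-eye-filter (NPWE) model
observer — together with a synthetic phantom generator that provides ground
truth for every quantity the pipeline estimates.

All images are axial slice stacks in Hounsfield units with known in-plane
pixel spacing and slice thickness. One fixed coordinate convention is shared
by every module: 0-based (row, col) indices, pixel centres at integer
coordinates, physical position = index × spacing.

## Noise power spectrum

For each square ROI and slice, a least-squares polynomial of total degree 2
(basis 1, x, y, x², xy, y²) is subtracted before the FFT; the 2D NPS is the
scaled average periodogram of the residuals over all (ROI, slice) pairs. The
detrend is the sole leakage control — no window function is applied — so the
estimator integrates exactly to the detrended pixel variance (Parseval),
which is why the noise magnitude is defined as the square root of the full
2D integral rather than of the 1D radial curve: that convention keeps the
magnitude in HU and equal to the noise SD.

Numerical choices:

* **Radial binning.** Bin width = the FFT grid spacing `1/(L·Δ)`; an annulus
  value is the plain mean of the 2D grid samples assigned to it (nearest-bin
  assignment, no interpolation).
* **Detrend side effect.** Removing six polynomial degrees of freedom
  suppresses the lowest frequency bin of the spectrum (roughly half of the
  first annulus for white noise). The DC bin is excluded from peak detection
  for the same reason, and validation of spectral flatness starts at the
  second annulus.
* **Peak detection.** A 3-point moving average precedes the extremum search.
  Maxima below a 0.05 mm⁻¹ cutoff are reported first as a low-frequency
  (cupping-artefact) peak, the global maximum above the cutoff as the noise
  texture peak; a monotonically decreasing profile returns its first
  interior bin flagged as a boundary peak. The cutoff separates the
  ~0.02 mm⁻¹ artefact peak seen in large-FOV CBCT from texture peaks at
  0.1–0.3 mm⁻¹.
* **Default ROI layout.** Four ROIs at 3, 6, 9 and 12 o'clock at the
  mid-radius (50 mm) of a 200 mm phantom disk; 82 px ROIs suit a ~280 mm
  FOV, 46 px the ~490 mm body FOVs.
* **Degenerate inputs.** Constant stacks return magnitude 0 and an empty
  peak list; ROIs smaller than 3×3 (degree-2 fit impossible), mixed ROI
  sizes and off-image ROIs are errors.

## Circular-edge TTF

The insert centre is refined to sub-pixel accuracy as the intensity-weighted
centroid of pixels passing a half-contrast threshold on the slice-averaged
image; the analysis then assigns every pixel inside the analysis disk its
exact radius from that centre and pools pixels across slices, giving a
radially oversampled ESF.

* **ESF bin width** defaults to spacing/10 — the circular edge provides
  enough radial phase diversity to support 10× oversampling.
* **Geometry defaults.** Analysis disk radius 2× insert radius; background
  annulus (1.3, 1.8)× insert radius; contrast measured in a disk of 60%
  insert radius. These are unconstrained by the protocol, so they are fixed
  here once.
* **LSF.** Central finite difference of the binned ESF; the sign is flipped
  for negative-contrast inserts so the lobe is positive; a Hann window
  centred on the LSF extremum with half-width 4× the LSF's own FWHM estimate
  suppresses far-from-edge noise. No noise-power subtraction is applied —
  slice pooling (default 40 slices) is the only noise control.
* **TTF and f50.** The TTF is the zero-padded FFT modulus of the windowed
  LSF normalised at DC; `f50` is the first downward 0.5 crossing by linear
  interpolation (the monotone first-crossing rule makes noisy TTFs
  well-defined). A TTF that never reaches 0.5 below the bin Nyquist yields
  `NA` with a warning, not an error.

The estimator is validated against closed forms: a Gaussian PSF of width σ
must give `TTF(f) = exp(−2π²σ²f²)` and `f50 = √(ln2/2)/(πσ)`, checked at
σ ∈ {0.3, 0.5, 1.0} mm to within 3% in the test suite, together with the
1/σ scaling of f50 and an independent brute-force convolution oracle for
the ESF. A small systematic error grows with σ/R (edge curvature); at
σ = 1 mm on a 12.2 mm insert it stays within the 3% band.

## NPWE observer

The task is a flat disk of 10 mm diameter at a prescribed signed contrast;
its Fourier transform `W` is evaluated analytically (Bessel J₁ form), so no
rasterisation error enters the task. The eye filter is the visual response
family `E(ρ) = ρⁿ exp(−cρ²)` in angular frequency with n = 1.3 and `c`
solved so E peaks at 4 cycles/degree, normalised to maximum 1 — the standard
parameterisation in task-based CT assessment; the display chain (viewing
distance 500 mm, zoom 1.5, display pixel pitch 0.2 mm) converts image
frequency to angular frequency. No internal-noise term is added (pure NPWE).
Absolute d′ values depend on these eye-filter constants; ratios and
orderings between reconstructions are insensitive to them to first order,
and only those are asserted.

Integration uses the trapezoid rule on the full square NPS frequency grid
up to its Nyquist; the TTF is applied radially (rotational symmetry) by
linear interpolation. The white-noise limit has the closed form
`d′ = |C|·r·√(π/N₀)`, which the test suite reproduces within 1% on a fine
grid, along with exact linearity in contrast and the √2 gain under NPS
halving. A NPS that is zero everywhere the task has support is rejected as
degenerate (d′ would be infinite).

## The synthetic phantom

The generator emulates a 200 mm Catphan-like phantom: a uniformity module
(background + optional cupping bowl + stationary correlated noise) and a
sensitometry module with four 12.2 mm cylindrical inserts at nominal
contrasts −1000 (air), −180 (LDPE), +235 (Delrin) and +790 HU (Teflon).
Defaults mirror the emulated acquisition protocol: 512×512 matrix, slice
thickness 1.991 mm, head-mode spacing 281.6/512 mm, 85 uniformity slices
(17 × 5 acquisitions) and 40 insert slices (8 × 5) per reconstruction.

**Noise synthesis.** Fourier-amplitude filtering of white Gaussian noise
under a radially symmetric target NPS, normalised on the synthesis grid so
the expected pixel variance equals the target σ² exactly; the DC bin is
zeroed. Noise is drawn independently per slice (axial slices are analysed
independently downstream). Two texture families are provided:
"FBP-like", `NPS(f) ∝ f·exp(−(f/f₀)²)` peaking at 0.29 mm⁻¹ by default, and
"IR-like", the same band-pass family with the peak moved to 0.20 mm⁻¹ and
(in use) a lower σ.

A low-pass IR family of the form `f·exp(−(f/f₀)³)` was evaluated and
rejected: with an IR σ 35% below FBP's, it concentrates the entire (smaller)
IR variance below ≈0.35 mm⁻¹, so the IR spectrum *exceeds* the FBP spectrum
across the low-frequency band where a 10 mm lesion task lives, and the NPWE
index then decreases under IR — the opposite of what is observed on real
systems, where the measured IR spectrum lies below the FBP spectrum
essentially everywhere. The shared-family choice preserves a high-frequency
tail and restores the correct ordering. Note the general caveat: a target σ
and peak frequency under-constrain the full spectral shape, so the
*magnitude* of the synthetic d′ gain (a few percent) is much smaller than
gains measured on real reconstructions; only the ordering is a meaningful
synthetic endpoint, and only the ordering is asserted.

**Inserts and blur.** Pixel values are point samples of the continuous
object convolved with the isotropic Gaussian PSF; the blurred-disk radial
profile is evaluated by a stabilised Bessel-I integral. Point sampling is
deliberate: CT pixels sample a continuous reconstruction, and modelling a
pixel-aperture average instead would fold an extra `sinc(πfΔ)` factor
(≈0.93 at f50 for σ = 0.5 mm, ≈0.82 for σ = 0.3 mm) into every measured
TTF, breaking the Gaussian closed form the generator is meant to provide.
In the σ = 0 limit the insert is the exact binary indicator, so a sharp
disk yields a step ESF confined to the bins straddling the radius.

**Cupping.** The optional artefact is a raised-cosine radial bowl of
prescribed centre depth spanning the phantom disk. A quadratic bowl was
rejected because a quadratic in x, y lies exactly in the degree-2 detrend
basis and would be removed identically, leaving no trace in the NPS; the
cosine profile is not polynomial and leaves low-frequency residual power
whose peak falls in the first radial bin (~0.02 mm⁻¹ at body-mode ROI
sizes). Because the bowl is static across slices, its residual power is
modest: at typical noise levels (σ ≈ 10 HU) a 30 HU bowl is buried under
the noise spectrum, so the low-frequency peak is exercised in tests on
noiseless stacks and on constructed profiles.

**What the generator does not emulate.** No projection/reconstruction
physics, scatter, beam hardening or detector model; no phantom boundary
(the uniformity field is unbounded); no inter-slice noise correlation; no
contrast- or dose-dependence of resolution (each synthetic reconstruction
has one PSF). Passing tests therefore demonstrate estimator correctness on
stationary Gaussian textures and ideal cylinders — not that any real
reconstruction behaves like its synthetic stand-in.

## Reporting conventions

Percent change is `100·(IR − FBP)/FBP`. The "mean ± SD over inserts" uses
the sample (n−1) standard deviation over the four per-insert percent
changes; with four points this is close to, but not identical with, a
half-range convention, and the sample-SD reading is the one implemented and
tested. Human-readable reports round percent values to integers; CSV output
keeps full precision. Each assessment writes a manifest (seed, slice
counts, package version) for reproducibility; identical configurations,
including seeds, produce bit-identical stacks and therefore identical
tables.

## Problem sizes

The validation suite runs the estimators at the protocol's native scale
where the quantity under test requires it (the end-to-end comparison uses a
512 matrix with 85 uniformity and 40 insert slices per reconstruction) and
at reduced scale (128–256 matrices, tens of slices) for unit-level checks,
chosen so each check's sampling error is several times smaller than the
tolerance it asserts.

## Known limitations

* The DICOM support is a minimal uncompressed explicit-VR little-endian
  subset (the CT tag set needed for calibrated slices); compressed or
  implicit-VR series are rejected.
* Absolute d′ values depend on the eye-filter parameterisation (exponent
  and peak angular frequency), for which different implementations use
  different constants; compare d′ across conditions, not across software.
* The TTF assumes a single circular insert within its analysis disk;
  closely spaced structures would corrupt the background annulus.
* The radial NPS peak is quantised to the annulus grid `1/(L·Δ)`; peak
  shifts smaller than one bin are not resolvable at a given ROI size.
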
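---
title: "Simulating and measuring stent appearance in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring stent appearance in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stentsim)
```

This vignette is the package's account of its science: what the simulation
models, which parameters matter and why their defaults are what they are,
the numerical choices inside the measurement operators, and what the
synthetic design can and cannot say about real scanners.

## The imaging model and its assumptions

A scanner is represented by a `system_config`: reconstruction FOV and
matrix (pixel pitch = FOV/N), slice thickness, an effective in-plane
Gaussian point-spread function (PSF), and white Gaussian quantum noise in
HU. `apply_system()` degrades a supersampled ground-truth volume in four
linear steps - PSF convolution, axial slab averaging, area-weighted pixel
binning, additive noise. The model is deliberately minimal:

- **Gaussian PSF.** Neither system's modulation transfer function is
  publicly characterized, so blur is a single effective FWHM per detector.
  Focal spot size is carried as metadata only; its geometric contribution
  is folded into the FWHM. Defaults are 0.30 mm for the photon-counting
  geometry and 0.60 mm for the energy-integrating one - about twice each
  system's 150-mm-FOV pixel pitch, the conventional rule of thumb for a
  well-matched reconstruction. We treat the PSF as a *detector* property,
  constant across reconstruction FOV: re-gridding the same raw data onto a
  smaller FOV changes sampling, not physics. Both values are overridable,
  and every directional claim in the tests is a comparison at fixed
  settings, not a claim about any particular commercial scanner.
- **Noise.** White, additive, 10 HU at the 9 mGy reference dose for both
  systems (the study design matched dose), scaled as `sqrt(9/CTDI_vol)`.
  Correlated reconstruction noise, streaks and photon starvation are not
  modelled; the stent metrics here are resolution-driven and the tests
  average noise over many profile samples.
- **Axial direction.** Output slices are contiguous means over the slice
  thickness. The phantom is axially uniform, so this mainly sets the noise
  and replication structure (three axial "locations" per stent).

`pixel_size()` and the four presets reproduce the documented grid values
(0.146 / 0.049 / 0.293 / 0.098 mm) exactly; these are arithmetic, not
model, quantities.

## The phantom generator

`phantom_spec()` describes a 20-cm agar cylinder (10 HU) holding a
contrast-filled artery at its centre: lumen at 390 HU (15 mg/mL iodinated
contrast at 120 kVp, ~26 HU per mg/mL), a 1-mm vessel wall at 50 HU, and
stents modelled as thin continuous annuli of 8000 HU metal,
0.15 mm radial strut thickness, centreline diameter `d`. The three built-in
specimens carry the calibrated ground truths: carotid `d = 5.5`, iliac
`d = 8.5`, and a femoral pair `d = 7` and `5.8` mm.

Deliberate simplifications, and what they imply for interpretation:

- The real device is a woven mesh in a radiolucent polymer cover; the
  annulus is its axial cross-section idealization. Per-strut texture,
  incomplete apposition and mesh periodicity are absent, so absolute
  diameter errors come out smaller than on real scans - comparisons
  between systems, not absolute errors, are the transferable quantity.
- The intertwined femoral pair is modelled as two rings whose axes are
  offset by 1.4 mm, placing the adjacent struts 0.8 mm apart on the
  inter-stent axis. That separation was chosen a priori from two-Gaussian
  resolvability: at 0.8 mm a 0.6-mm-FWHM system is partially merged while
  a 0.3-mm-FWHM system resolves the gap - the regime the ex vivo
  experiment reports. It is a generator constant, not a fitted value.
- Metal is rasterized at <= 0.02 mm pitch (`fine_spacing()` picks an exact
  integer fraction of the output pixel, at least 3x finer), so the thin
  annulus area is correct to ~2% before degradation.

## Measurement operators and numerical choices

All three metrics work on bilinearly interpolated HU profiles
(`extract_profile()`, step = pixel/4 by default, symmetric about the line
centre) and subpixel peaks (`find_peaks_subpixel()`: interior local maxima
filtered by topographic prominence, position refined by the parabola
through the three samples around the maximum, refinement clamped to half a
step).

- **Centroid.** The stent centre is re-estimated per slice as the
  intensity-weighted centroid of voxels above halfway between the local
  background (box median) and maximum, iterated once. For the intertwined
  pair this is disabled (the neighbour biases it) and the known generator
  centres are used - mirroring the ex vivo protocol, where the analyst
  knows where each stent is.
- **Diameter.** Per line, the distance between the two opposing strut
  peaks. With a neighbouring stent in the lumen, the peak nearest the
  expected radius (window 0.45 mm) is selected instead of the outermost
  one, and lines are restricted to arcs where the two rings' crossings
  stay well separated (for the femoral geometry: diametral lines at
  70-110 degrees for the 7-mm ring, -20 to 20 degrees for the 5.8-mm ring,
  from the circle-circle intersection geometry). Lines without a usable
  pair are excluded; more than 50% exclusions abort the measurement.
- **Blooming.** Radial rays from the centroid; local background is the
  median HU 0.6-1.2 mm inside the strut peak (lumen side); the half-maximum
  level is background + (peak - background)/2; inner and outer crossings
  are linearly interpolated between samples. Crossings not bracketed
  exclude the ray. Per slice, the angular mean radii give
  `A_in`/`A_out` and blooming = (A_out - A_in)/A_out x 100, which is
  bounded in [0, 100] by construction. The half-maximum delineation is the
  standard surrogate for the region-of-interest protocol used at the
  workstation, which is not reproducible from its description.
- **Distinction.** One profile along the inter-stent axis; the two
  adjacent strut peaks are matched to their expected positions (window
  0.5 mm); `peak` is their mean height (symmetric treatment of unequal
  peaks), `trough` the sample minimum between them, `minimum` the mean HU
  in an agar annulus 2-3 stent radii from the vessel centre. A location
  whose two struts have merged into one detected peak scores 0 and is
  flagged. The index is clamped to [0, 100].
- **Windowing independence.** All metrics operate on raw HU; display
  window settings affect none of them, and all three are invariant to
  affine HU rescaling (checked by test).

## Statistics layer

`wilcoxon_signed_rank()` drops zero differences, mid-ranks ties, and is
exact (full sign-assignment null) iff at most 15 non-zero differences
remain and none are tied, otherwise it uses the tie- and
continuity-corrected normal approximation; the exact path is verified
against an independent brute-force enumeration oracle. `paired_t()` and
`normality_check()` carry the classical definitions; zero-variance input
is a diagnosed error (except inside `summarize_comparison()`, where two
identical arms legitimately summarize to p = 1). `icc_consistency()`
computes ICC(C,k) from two-way mean squares and is cross-checked against
an independent ANOVA decomposition; quartiles use the linear-interpolation
definition of mainstream statistics software.

One calibration design note: the Monte-Carlo type-I check runs the t-test
at n = 9 and the Wilcoxon at n = 20. The exact signed-rank test is
discrete; at n = 9 its largest attainable two-sided size below 0.05 is
0.039, so no implementation could land in a [0.04, 0.06] band there. At
n = 20 (approximate path) the attainable size is 0.048. These sizes were
computed from the signed-rank null distribution before the tests were
written.

## Reader-study simulation

`simulate_reader_scores()` draws 5-point Likert scores from a latent
cumulative model: score = 1 + number of thresholds below latent + reader
bias + Gaussian perceptual noise, two readers and two sessions. In the
experiment driver the latent quality per image derives from the *measured*
metrics of that system (blooming maps through `(28 - blooming%)/7`,
distinction through `(distinction% - 65)/15`, overall appearance through
the mean of the blooming scale and `(0.45 - error)/0.18`), so the ordinal
layer inherits the physics rather than being scripted. Perceptual noise
defaults to 1.3 latent units with a 0.4 inter-reader bias - readers who
disagree by over a Likert point on a typical image - which places
simulated reliability at the good/moderate boundary rather than at the
near-perfect agreement a small noise value would give; human reader
studies of this task report moderate agreement. These are generator
conventions: the reliability layer demonstrates the ICC machinery, not a
claim about any particular pair of radiologists.

## Problem sizes and determinism

The default experiment is 3 specimens x 4 presets, three axial locations
per stent and eight profile lines per location; a full run takes well
under a minute on one core. Every random draw (noise, reader scores) is
seeded from one master seed by a fixed counter scheme
(`master_seed * 1000 + volume index`), so identical configurations produce
byte-identical summary files; the test suite and `scripts/acceptance.R`
use reduced or shared renderings where replication over seeds is needed.

## Known limitations

No physical x-ray transport: no beam hardening, metal streaks, photon
starvation, spectral effects or reconstruction-kernel ringing; motion is
absent. Stent geometry is an idealized annulus. Consequently absolute
metric values - especially absolute diameter error - are optimistic
relative to real scans, while orderings under resolution changes (blooming
non-decreasing in FWHM, distinction non-increasing, the sharper system
winning on all three metrics) are the supported conclusions, and are the
properties the acceptance suite checks.
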
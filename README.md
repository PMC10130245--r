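# stentsim

Vascular stents are routinely followed up with CT, but the metal struts
*bloom*: blur and partial-volume averaging make them look thicker than they
are, which inflates measured stent diameters, hides the in-stent lumen and
can make two intertwined stents merge into one. How much a given scanner
blooms is a spatial-resolution question, and it is the key quantity when
comparing a high-resolution photon-counting CT (PCCT) detector against a
conventional energy-integrating detector (EID).

`stentsim` is an R package for studying this in silico. It is written for
imaging physicists and methodologists who want a fully synthetic,
reproducible version of the classic ex vivo experiment: a stented,
contrast-filled artery embedded in a 20-cm soft-tissue-equivalent cylinder,
imaged by two systems at matched dose, and scored with profile-based stent
metrics plus a simulated reader study. Every stage runs from code - no scan
data is required.

## The model

**Imaging.** A scanner configuration is reduced to the parameters that
matter for stent appearance: reconstruction field of view and matrix (hence
pixel size FOV/N), slice thickness, an effective in-plane Gaussian
point-spread function with full width at half maximum `f`, and white
quantum noise with standard deviation sigma_HU scaled as
`sqrt(9 mGy / CTDI_vol)`. A supersampled ground-truth phantom (material HU
per voxel) is degraded by PSF convolution, axial slab averaging, detector
pixel binning, then noise. Four presets pair a silicon photon-counting
geometry (1024 x 1024, 0.42 mm slices) and an energy-integrating geometry
(512 x 512, 0.63 mm slices) with 150-mm and 50-mm FOV reconstructions.

**Metrics.** On axial slices, HU line profiles through the stent centroid
give, per replicate location (three per stent):

- *diameter* - the peak-to-peak distance between the two opposing strut
  maxima, each refined to subpixel precision by parabolic interpolation,
  reported against the ground-truth ring diameter `d` as mean absolute
  error;
- *blooming* - from radial profiles, the half-maximum inner and outer
  crossing radii define apparent areas `A_in = pi r_in^2`,
  `A_out = pi r_out^2`, and blooming = `(A_out - A_in) / A_out x 100%`;
- *inter-stent distinction* - for two intertwined stents, with `peak` the
  mean of the two adjacent strut maxima, `trough` the HU minimum between
  them and `min` the background far from the vessel, distinction =
  `(peak - trough) / (peak - min) x 100%` (100 = fully separated, 0 =
  merged).

**Statistics.** Paired t-tests compare the continuous metrics between
systems; simulated 5-point Likert reader scores are compared with the
Wilcoxon signed-rank test (exact by enumeration for small tie-free samples)
and reader reliability is summarized with the two-way consistency
intraclass correlation for the mean of two raters,
ICC(C,2) = (MS_items - MS_error) / MS_items.

## Worked example

Image the carotid specimen (5.5 mm stent) with the photon-counting preset
and measure it:

```r
library(stentsim)

cfg  <- preset_config("si_pcct_150")
cfg
#> <system_config> si_pcct_150
#>   FOV 150 mm, matrix 1024, pixel 0.146 mm, slice 0.42 mm
#>   PSF FWHM 0.3 mm, noise 10 HU @ 9 mGy, CTDI_vol 8.9 mGy

spec  <- phantom_preset("carotid")
truth <- rasterize_phantom(spec, fine_spacing(cfg), n_slices = 3,
                           slice_spacing_mm = cfg$slice_thickness_mm)
vol   <- apply_system(truth, cfg, seed = 42)
vol
#> <image_volume> 105 x 105 x 3 voxels, spacing 0.1465 x 0.1465 x 0.42 mm
#>   HU range [-30.7, 3638.1]

d <- measure_diameter(vol, c(0, 0), 1:3, expected_diameter_mm = 5.5)
b <- measure_blooming(vol, c(0, 0), 1:3, expected_diameter_mm = 5.5)
sprintf("diameter %.2f +/- %.2f mm (true 5.5); blooming %.1f +/- %.1f %%",
        d$mean, d$sd, b$mean, b$sd)
#> [1] "diameter 5.46 +/- 0.05 mm (true 5.5); blooming 23.0 +/- 0.1 %"
```

The measured diameter sits within a pixel of the 5.5 mm ground truth, and
about 23% of the apparent strut annulus area is blooming. Re-running with
the energy-integrating preset (`eidct_150`) roughly doubles both the
diameter error and the blooming - the resolution story the package exists
to quantify. `run_experiment(experiment_config())` runs the full design
(three specimens, four presets, reader simulation) and writes tidy
per-location CSVs, NIfTI volumes and a summary report; the same pipeline is
scriptable through the `stentsim` CLI
(`system.file("cli", "stentsim", package = "stentsim")`) with subcommands
`generate`, `image`, `measure`, `compare` and `run-all`.

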
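test_that("rasterization assigns materials by region membership", {
  spec <- phantom_preset("carotid")
  vol <- rasterize_phantom(spec, 0.01, extent_mm = 8, n_slices = 1L)
  xc <- vol$origin_mm[1] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing_mm[1]
  at <- function(x, y) vol$voxels[which.min(abs(xc - x)), which.min(abs(xc - y)), 1]
  expect_equal(at(0, 0), spec$lumen_hu)             # vessel centre
  expect_equal(at(2.75, 0), spec$metal_hu)          # annulus centreline
  expect_equal(at(0, 2.75), spec$metal_hu)
  expect_equal(at(0, 3.74), spec$lumen_hu)          # inside lumen, off ring
})

test_that("rasterized annulus area matches the analytic thin-ring area", {
  d <- 5.5; t <- 0.15
  spec <- phantom_preset("carotid")
  vol <- rasterize_phantom(spec, 0.008, extent_mm = 7, n_slices = 1L)
  n_metal <- sum(vol$voxels[, , 1] == spec$metal_hu)
  area <- n_metal * 0.008^2
  expect_lt(abs(area - pi * d * t) / (pi * d * t), 0.02)
})

test_that("impossible geometry and HU orderings are rejected", {
  expect_error(phantom_spec(stent_spec(7.6), vessel_lumen_diameter_mm = 7.5),
               "geometry")
  expect_error(stent_spec(0.2, strut_thickness_mm = 0.15), "twice")
  expect_error(stent_spec(5, strut_thickness_mm = -1), "positive")
  expect_error(phantom_spec(stent_spec(5), vessel_lumen_diameter_mm = 7,
                            lumen_hu = 5, background_hu = 10), "ordering")
  expect_error(rasterize_phantom(phantom_preset("iliac"), 0.05), "0.02")
})

test_that("a degenerate chain (no blur, no binning, no noise) is the identity", {
  arr <- array(stats::rnorm(32 * 32 * 2, 100, 50), c(32, 32, 2))
  truth <- image_volume(arr, spacing_mm = c(0.5, 0.5, 0.5))
  cfg <- system_config("ident", fov_mm = 16, matrix_n = 32,
                       slice_thickness_mm = 0.5, psf_fwhm_mm = 0)
  out <- apply_system(truth, cfg, add_noise = FALSE)
  expect_equal(out$voxels, truth$voxels, tolerance = 1e-12)
  expect_equal(out$spacing_mm, truth$spacing_mm)
})

test_that("imaging preserves a uniform field and the volume mean", {
  cfg <- preset_config("si_pcct_150")
  fs <- fine_spacing(cfg)
  v0 <- 123
  truth <- image_volume(array(v0, c(400, 400, 1)),
                        spacing_mm = c(fs, fs, cfg$slice_thickness_mm))
  out <- apply_system(truth, cfg, seed = 11)
  sd_eff <- cfg$noise_sd_hu * sqrt(9 / cfg$ctdi_vol_mgy)
  expect_lt(abs(mean(out$voxels) - v0),
            3 * sd_eff / sqrt(length(out$voxels)))

  # material conservation on a structured phantom, noiseless
  spec <- phantom_preset("carotid")
  n_out <- 100L
  k <- round(cfg$pixel_mm / fs)
  extent <- n_out * cfg$pixel_mm
  tr <- rasterize_phantom(spec, fs, extent_mm = extent, n_slices = 1L,
                          slice_spacing_mm = cfg$slice_thickness_mm)
  expect_true(dim(tr$voxels)[1] %% k == 0)
  out2 <- apply_system(tr, cfg, add_noise = FALSE)
  expect_lt(abs(mean(out2$voxels) - mean(tr$voxels)), 0.5)
})

test_that("simulated noise has the configured standard deviation", {
  cfg <- preset_config("eidct_150", noise_sd_hu = 10, ctdi_vol_mgy = 9)
  fs <- cfg$pixel_mm / 3
  truth <- image_volume(array(0, c(330, 330, 1)),
                        spacing_mm = c(fs, fs, cfg$slice_thickness_mm))
  out <- apply_system(truth, cfg, seed = 5)
  expect_gte(length(out$voxels), 1e4)
  expect_gt(stats::sd(out$voxels), 9.5)
  expect_lt(stats::sd(out$voxels), 10.5)
  # dose scaling: 4x the dose halves the noise
  cfg2 <- preset_config("eidct_150", noise_sd_hu = 10, ctdi_vol_mgy = 36)
  out2 <- apply_system(truth, cfg2, seed = 5)
  expect_lt(abs(stats::sd(out2$voxels) - 5), 0.3)
})

test_that("stronger blur monotonically dilutes the strut peak", {
  spec <- phantom_preset("carotid")
  cfg0 <- preset_config("eidct_150")
  fs <- fine_spacing(cfg0)
  truth <- rasterize_phantom(spec, fs, extent_mm = 10, n_slices = 1L,
                             slice_spacing_mm = cfg0$slice_thickness_mm)
  peaks <- vapply(c(0.2, 0.4, 0.8), function(f) {
    cfg <- preset_config("eidct_150", psf_fwhm_mm = f)
    max(apply_system(truth, cfg, add_noise = FALSE)$voxels)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("identical phantom, system and seed give bit-identical volumes", {
  cfg <- preset_config("si_pcct_50")
  v1 <- ring_volume(5.5, cfg, seed = 123)
  v2 <- ring_volume(5.5, cfg, seed = 123)
  v3 <- ring_volume(5.5, cfg, seed = 124)
  expect_identical(v1$voxels, v2$voxels)
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("oversampling and commensurability violations are refused", {
  cfg <- preset_config("si_pcct_150")
  coarse <- image_volume(array(0, c(20, 20, 1)),
                         spacing_mm = c(0.1, 0.1, cfg$slice_thickness_mm))
  expect_error(apply_system(coarse, cfg), "resolution error")
  bad_z <- image_volume(array(0, c(60, 60, 2)),
                        spacing_mm = c(cfg$pixel_mm / 4, cfg$pixel_mm / 4, 0.25))
  expect_error(apply_system(bad_z, cfg), "resolution error")
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  vol <- image_volume(array(stats::rnorm(10 * 12 * 3), c(10, 12, 3)),
                      spacing_mm = c(0.25, 0.25, 0.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, f)
  back <- read_volume_nifti(f)
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
})
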
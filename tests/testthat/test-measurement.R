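test_that("diameter is recovered from a noiseless sharp annulus", {
  cfg <- preset_config("si_pcct_150", psf_fwhm_mm = 1e-6)
  vol <- ring_volume(5.5, cfg)
  md <- measure_diameter(vol, c(0, 0), 1L, expected_diameter_mm = 5.5)
  expect_lt(abs(md$mean - 5.5), cfg$pixel_mm)
  expect_identical(md$n_excluded, 0L)
})

test_that("blurred-ring diameters track the analytic convolution oracle", {
  # A symmetric PSF leaves the peak-to-peak distance at the blurred ring's
  # analytic peak radius (which sits a few microns inside d/2 because of
  # ring curvature); the measured diameter must match the dense numerical
  # convolution oracle within one profile step, and the truth within a pixel.
  for (f in c(0.3, 0.6)) {
    cfg <- preset_config("si_pcct_150", psf_fwhm_mm = f)
    vol <- ring_volume(5.5, cfg)
    step <- cfg$pixel_mm / 4
    md <- measure_diameter(vol, c(0, 0), 1L, expected_diameter_mm = 5.5)
    oracle <- dense_peak(function(x)
      ring_conv_profile(x, 0, 2.75, fwhm_to_sigma(f)), 2, 3.5)
    expect_lt(abs(md$mean - 2 * oracle$position), step,
              label = sprintf("fwhm %.1f: %.4f vs oracle %.4f",
                              f, md$mean, 2 * oracle$position))
    expect_lt(abs(md$mean - 5.5), cfg$pixel_mm)
  }
})

test_that("intertwined stents are measured separately on restricted arcs", {
  spec <- phantom_preset("femoral")
  cfg <- preset_config("si_pcct_150")
  truth <- rasterize_phantom(spec, fine_spacing(cfg), extent_mm = 22,
                             n_slices = 1L,
                             slice_spacing_mm = cfg$slice_thickness_mm)
  vol <- apply_system(truth, cfg, add_noise = FALSE)
  arcs <- attr(spec, "measure_arcs")
  truths <- c(7, 5.8)
  for (i in 1:2) {
    md <- measure_diameter(vol, spec$stents[[i]]$center_offset_mm, 1L,
                           angles_deg = arcs[[i]]$diametral_deg,
                           n_angles = 8L,
                           expected_diameter_mm = truths[i],
                           refine_center = FALSE)
    expect_lt(abs(md$mean - truths[i]), cfg$pixel_mm,
              label = sprintf("stent %d: %.3f vs %.1f", i, md$mean, truths[i]))
  }
})

test_that("mean absolute error is plain arithmetic with guarded input", {
  expect_identical(mean_abs_error(c(5.5, 5.5), 5.5), 0)
  expect_equal(mean_abs_error(c(5.4, 5.8), 5.5), 0.2)
  expect_error(mean_abs_error(numeric(0), 5.5), "non-empty")
  expect_error(mean_abs_error(c(5, NA), 5.5), "finite")
})

test_that("blooming and distinction formulas match hand arithmetic", {
  expect_identical(blooming_from_areas(80, 100), 20)
  expect_identical(blooming_from_areas(100, 100), 0)
  expect_error(blooming_from_areas(120, 100), "exceed")
  expect_error(blooming_from_areas(-1, 100), "positive")
  set.seed(4)
  ai <- runif(50, 0, 50); ao <- ai + runif(50, 0, 50)
  b <- blooming_from_areas(ai, ao)
  expect_true(all(b >= 0 & b <= 100))
  expect_equal(b, (ao - ai) / ao * 100)

  expect_identical(distinction_index(1000, 10, 10), 100)
  expect_identical(distinction_index(1000, 1000, 10), 0)
  expect_equal(distinction_index(900, 500, 100), 50)
  expect_error(distinction_index(100, 50, 100), "exceed")
  set.seed(5)
  mn <- runif(30, 0, 50); pk <- mn + runif(30, 1, 2000)
  tr <- mn + (pk - mn) * runif(30)
  expect_true(all(distinction_index(pk, tr, mn) >= 0 &
                    distinction_index(pk, tr, mn) <= 100))
})

test_that("blooming grows with blur and distinction shrinks with blur", {
  spec <- single_stent_phantom(8.5)
  cfg0 <- preset_config("si_pcct_150")
  truth <- rasterize_phantom(spec, fine_spacing(cfg0), n_slices = 1L,
                             slice_spacing_mm = cfg0$slice_thickness_mm)
  bl <- vapply(c(0.3, 0.6), function(f) {
    vol <- apply_system(truth, preset_config("si_pcct_150", psf_fwhm_mm = f),
                        add_noise = FALSE)
    measure_blooming(vol, c(0, 0), 1L, expected_diameter_mm = 8.5)$mean
  }, numeric(1))
  expect_lt(bl[1], bl[2])

  fem <- phantom_preset("femoral")
  ftruth <- rasterize_phantom(fem, fine_spacing(cfg0), extent_mm = 22,
                              n_slices = 1L,
                              slice_spacing_mm = cfg0$slice_thickness_mm)
  di <- vapply(c(0.3, 0.45, 0.6), function(f) {
    vol <- apply_system(truth = ftruth,
                        preset_config("si_pcct_150", psf_fwhm_mm = f),
                        add_noise = FALSE)
    measure_distinction(vol, c(-0.7, 0), c(0.7, 0), 7, 5.8, 1L,
                        gap_angle = 0)$mean
  }, numeric(1))
  expect_true(all(diff(di) <= 1e-9))
})

test_that("half-maximum radii and trough match the 1-D convolution oracle", {
  sigma <- fwhm_to_sigma(0.5)
  R <- 2.75
  f <- function(x) 2000 * ring_conv_profile(x, 0, R, sigma)
  step <- 0.06
  r <- seq(0, 4.5, by = step)
  prof <- line_profile(r, f(r))
  pk <- find_peaks_subpixel(prof, 50)
  oracle <- dense_peak(f, 1.5, 4)
  expect_lt(abs(pk$position_mm[which.max(pk$height_hu)] - oracle$position),
            step)
  level <- 0.5 * oracle$height
  got <- stentsim:::.half_max_crossings(r, prof$hu, oracle$position, level)
  want <- dense_half_max_crossings(oracle$x, oracle$y,
                                   which.max(oracle$y), level)
  expect_lt(abs(got[1] - want["inner"]), step)
  expect_lt(abs(got[2] - want["outer"]), step)
})

test_that("all three metrics are invariant to affine HU rescaling", {
  cfg <- preset_config("eidct_150")
  spec <- phantom_preset("femoral")
  truth <- rasterize_phantom(spec, fine_spacing(cfg), extent_mm = 22,
                             n_slices = 1L,
                             slice_spacing_mm = cfg$slice_thickness_mm)
  vol <- apply_system(truth, cfg, add_noise = FALSE)
  a <- 2.5; b <- 300
  vol2 <- vol; vol2$voxels <- a * vol$voxels + b
  arcs <- attr(spec, "measure_arcs")

  d1 <- measure_diameter(vol, c(-0.7, 0), 1L, angles_deg = arcs[[1]]$diametral_deg,
                         n_angles = 6L, expected_diameter_mm = 7,
                         refine_center = FALSE, min_prominence_hu = 150)
  d2 <- measure_diameter(vol2, c(-0.7, 0), 1L, angles_deg = arcs[[1]]$diametral_deg,
                         n_angles = 6L, expected_diameter_mm = 7,
                         refine_center = FALSE, min_prominence_hu = 150 * a)
  expect_equal(d1$mean, d2$mean, tolerance = 1e-9)

  b1 <- measure_blooming(vol, c(-0.7, 0), 1L, expected_diameter_mm = 7,
                         angles_deg = arcs[[1]]$radial_deg, n_angles = 6L,
                         refine_center = FALSE)
  b2 <- measure_blooming(vol2, c(-0.7, 0), 1L, expected_diameter_mm = 7,
                         angles_deg = arcs[[1]]$radial_deg, n_angles = 6L,
                         refine_center = FALSE, min_prominence_hu = 150 * a)
  expect_equal(b1$mean, b2$mean, tolerance = 1e-9)

  s1 <- measure_distinction(vol, c(-0.7, 0), c(0.7, 0), 7, 5.8, 1L,
                            gap_angle = 0)
  s2 <- measure_distinction(vol2, c(-0.7, 0), c(0.7, 0), 7, 5.8, 1L,
                            gap_angle = 0, min_prominence_hu = 150 * a)
  expect_equal(s1$mean, s2$mean, tolerance = 1e-9)
})

test_that("featureless images abort diameter measurement cleanly", {
  vol <- image_volume(array(10, c(80, 80, 1)), spacing_mm = c(0.2, 0.2, 0.5))
  expect_error(
    measure_diameter(vol, c(0, 0), 1L, expected_diameter_mm = 5,
                     refine_center = FALSE),
    "measurement-failure")
})

test_that("fully merged struts score zero distinction and are flagged", {
  cfg <- preset_config("eidct_150", psf_fwhm_mm = 2.0)  # extreme blur
  spec <- phantom_preset("femoral")
  truth <- rasterize_phantom(spec, fine_spacing(cfg), extent_mm = 22,
                             n_slices = 1L,
                             slice_spacing_mm = cfg$slice_thickness_mm)
  vol <- apply_system(truth, cfg, add_noise = FALSE)
  dd <- measure_distinction(vol, c(-0.7, 0), c(0.7, 0), 7, 5.8, 1L,
                            gap_angle = 0)
  expect_identical(dd$per_location$distinction_pct, 0)
  expect_true(all(dd$per_location$merged))
})
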
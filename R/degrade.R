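#' Supersampling pitch matched to a detector grid
#'
#' Returns an in-plane rasterization pitch that divides the configuration's
#' pixel size exactly (so binning is an exact block mean), is at most
#' `max_spacing_mm`, and is at least a factor 3 finer than the pixel.
#'
#' @param cfg A `system_config`.
#' @param max_spacing_mm Upper bound on the pitch (mm).
#' @return Pitch in mm.
#' @export
fine_spacing <- function(cfg, max_spacing_mm = 0.02) {
  stopifnot(inherits(cfg, "system_config"))
  k <- max(3L, as.integer(ceiling(cfg$pixel_mm / max_spacing_mm)))
  cfg$pixel_mm / k
}

gaussian_kernel_2d <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_px)))
  g <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  g <- g / sum(g)
  outer(g, g)
}

# Exact block mean of a matrix over k x k tiles; dimensions must be
# multiples of k.
block_mean <- function(x, k) {
  if (k == 1L) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(n1 %% k == 0L, n2 %% k == 0L)
  x <- colMeans(array(x, c(k, n1 %/% k, n2)), dims = 1)      # (n1/k) x n2
  t(colMeans(array(t(x), c(k, n2 %/% k, n1 %/% k)), dims = 1))
}

#' Image a ground-truth volume through a system configuration
#'
#' Applies the linear degradation chain of one scanner configuration to a
#' supersampled ground-truth volume: (1) in-plane convolution with a
#' Gaussian point-spread function of FWHM `cfg$psf_fwhm_mm`; (2) axial
#' averaging over `cfg$slice_thickness_mm` (contiguous, non-overlapping
#' slabs); (3) area-averaging (block binning) onto the detector pixel grid;
#' (4) additive white Gaussian quantum noise with standard deviation
#' `cfg$noise_sd_hu * sqrt(9 / cfg$ctdi_vol_mgy)`.
#'
#' The truth grid must be commensurate with the output grid: its in-plane
#' pitch an integer fraction of `cfg$pixel_mm` (and at most a third of it
#' whenever blurring or binning occurs), its axial pitch an integer fraction
#' of the slice thickness. [fine_spacing()] produces a compliant pitch.
#'
#' @param truth An `image_volume` from [rasterize_phantom()].
#' @param cfg A `system_config`.
#' @param seed Integer seed making the noise draw reproducible; with the
#'   default `NULL` the current RNG state is used.
#' @param add_noise Set `FALSE` for a noiseless (deterministic) rendering.
#' @return An `image_volume` with spacing
#'   `(pixel_mm, pixel_mm, slice_thickness_mm)`.
#' @export
apply_system <- function(truth, cfg, seed = NULL, add_noise = TRUE) {
  stopifnot(inherits(truth, "image_volume"), inherits(cfg, "system_config"))
  dx <- truth$spacing_mm[1]
  if (abs(truth$spacing_mm[2] - dx) > 1e-9) {
    stop("resolution error: truth grid must be square in-plane", call. = FALSE)
  }
  k <- as.integer(round(cfg$pixel_mm / dx))
  if (k < 1L || abs(k * dx - cfg$pixel_mm) > 1e-6 * cfg$pixel_mm) {
    stop("resolution error: truth pitch is not an integer fraction of pixel_mm",
         call. = FALSE)
  }
  if ((cfg$psf_fwhm_mm > 0 || k > 1L) && dx > cfg$pixel_mm / 3 + 1e-9) {
    stop("resolution error: truth pitch must be <= pixel_mm / 3 for imaging",
         call. = FALSE)
  }
  dz <- truth$spacing_mm[3]
  g <- as.integer(round(cfg$slice_thickness_mm / dz))
  if (g < 1L || abs(g * dz - cfg$slice_thickness_mm) > 1e-6 * cfg$slice_thickness_mm) {
    stop("resolution error: axial pitch is not an integer fraction of slice thickness",
         call. = FALSE)
  }
  d <- dim(truth$voxels)
  nz_out <- d[3] %/% g
  if (nz_out < 1L) {
    stop("resolution error: too few axial samples for one output slice",
         call. = FALSE)
  }

  kern <- if (cfg$psf_fwhm_mm > 0) {
    sigma_px <- cfg$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / dx
    gaussian_kernel_2d(sigma_px)
  } else NULL

  # in-plane crop so dimensions are multiples of k (kept centred)
  off1 <- ((d[1] %% k) %/% 2L)
  off2 <- ((d[2] %% k) %/% 2L)
  n1 <- (d[1] %/% k) * k
  n2 <- (d[2] %/% k) * k
  i1 <- off1 + seq_len(n1)
  i2 <- off2 + seq_len(n2)

  out <- array(0, c(n1 %/% k, n2 %/% k, nz_out))
  for (z in seq_len(nz_out)) {
    slab <- truth$voxels[, , (z - 1L) * g + seq_len(g), drop = FALSE]
    sl <- rowMeans(slab, dims = 2)
    if (!is.null(kern)) {
      sl <- EBImage::filter2(sl, kern, boundary = "replicate")
    }
    out[, , z] <- block_mean(sl[i1, i2], k)
  }

  origin <- c(
    truth$origin_mm[1] + (off1 + (k - 1) / 2) * dx,
    truth$origin_mm[2] + (off2 + (k - 1) / 2) * dx,
    truth$origin_mm[3] + (g - 1) / 2 * dz
  )
  vol <- image_volume(out, spacing_mm = c(cfg$pixel_mm, cfg$pixel_mm,
                                          cfg$slice_thickness_mm),
                      origin_mm = origin)
  if (add_noise) {
    sd_eff <- cfg$noise_sd_hu * sqrt(9 / cfg$ctdi_vol_mgy)
    vol <- add_hu_noise(vol, sd_eff, seed = seed)
  }
  vol
}

#' Add white Gaussian HU noise to a volume
#'
#' @param vol An `image_volume`.
#' @param sd_hu Noise standard deviation in HU (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return The noisy `image_volume`.
#' @export
add_hu_noise <- function(vol, sd_hu, seed = NULL) {
  stopifnot(inherits(vol, "image_volume"), is.finite(sd_hu), sd_hu >= 0)
  if (sd_hu == 0) return(vol)
  draw <- function() stats::rnorm(length(vol$voxels), 0, sd_hu)
  eps <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  vol$voxels <- vol$voxels + array(eps, dim(vol$voxels))
  vol
}
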
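#' In-plane pixel size of a reconstruction
#'
#' CT reconstructions sample the field of view (FOV) onto a square matrix, so
#' the in-plane pixel pitch is simply `fov_mm / matrix_n`.
#'
#' @param fov_mm Reconstruction field of view per axis, in mm (> 0).
#' @param matrix_n Number of pixels per axis (integer >= 1).
#' @return Pixel size in mm.
#' @examples
#' pixel_size(150, 1024)  # 0.146 mm
#' pixel_size(50, 512)    # 0.098 mm
#' @export
pixel_size <- function(fov_mm, matrix_n) {
  if (!is.numeric(fov_mm) || length(fov_mm) != 1L || !is.finite(fov_mm) ||
      fov_mm <= 0) {
    stop("`fov_mm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(matrix_n) || length(matrix_n) != 1L || !is.finite(matrix_n) ||
      matrix_n < 1 || matrix_n != round(matrix_n)) {
    stop("`matrix_n` must be a single positive integer", call. = FALSE)
  }
  fov_mm / matrix_n
}

#' Imaging-system configuration
#'
#' Bundles the acquisition/reconstruction parameters of one scanner
#' configuration. The resolution-forming parameters (`psf_fwhm_mm`,
#' `slice_thickness_mm`, pixel grid) drive the image degradation model in
#' [apply_system()]; the remaining entries (focal spot, kVp) are carried as
#' metadata.
#'
#' @param label Short identifier for the configuration.
#' @param fov_mm Reconstruction field of view per axis (mm).
#' @param matrix_n Reconstruction matrix size per axis.
#' @param slice_thickness_mm Reconstructed slice thickness (mm).
#' @param psf_fwhm_mm Full width at half maximum of the in-plane Gaussian
#'   point-spread function (mm). This is a free model parameter: scanners are
#'   characterized here only through an effective blur.
#' @param noise_sd_hu Quantum-noise standard deviation in HU at the 9 mGy
#'   reference dose. Noise at other doses scales as `sqrt(9 / ctdi_vol_mgy)`.
#' @param ctdi_vol_mgy Volumetric CT dose index (mGy).
#' @param focal_spot_mm Focal spot size (mm); metadata only, its blur
#'   contribution is folded into `psf_fwhm_mm`.
#' @param tube_kvp Tube voltage (kVp); metadata only.
#' @return An object of class `system_config`.
#' @seealso [preset_config()] for the four study presets.
#' @export
system_config <- function(label, fov_mm, matrix_n, slice_thickness_mm,
                          psf_fwhm_mm, noise_sd_hu = 10, ctdi_vol_mgy = 9,
                          focal_spot_mm = NA_real_, tube_kvp = NA_real_) {
  cfg <- structure(
    list(
      label = as.character(label),
      fov_mm = as.numeric(fov_mm),
      matrix_n = as.integer(matrix_n),
      pixel_mm = pixel_size(fov_mm, matrix_n),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      psf_fwhm_mm = as.numeric(psf_fwhm_mm),
      noise_sd_hu = as.numeric(noise_sd_hu),
      ctdi_vol_mgy = as.numeric(ctdi_vol_mgy),
      focal_spot_mm = as.numeric(focal_spot_mm),
      tube_kvp = as.numeric(tube_kvp)
    ),
    class = "system_config"
  )
  validate_system_config(cfg)
}

validate_system_config <- function(cfg) {
  stopifnot(inherits(cfg, "system_config"))
  pos <- c("fov_mm", "slice_thickness_mm", "noise_sd_hu", "ctdi_vol_mgy")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("`%s` must be strictly positive", f), call. = FALSE)
    }
  }
  if (!is.finite(cfg$psf_fwhm_mm) || cfg$psf_fwhm_mm < 0) {
    stop("`psf_fwhm_mm` must be non-negative", call. = FALSE)
  }
  if (cfg$matrix_n < 2L) stop("`matrix_n` must be >= 2", call. = FALSE)
  if (abs(cfg$pixel_mm - cfg$fov_mm / cfg$matrix_n) > 1e-12) {
    stop("`pixel_mm` inconsistent with fov_mm / matrix_n", call. = FALSE)
  }
  cfg
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf("<system_config> %s\n", x$label))
  cat(sprintf("  FOV %g mm, matrix %d, pixel %.3f mm, slice %g mm\n",
              x$fov_mm, x$matrix_n, x$pixel_mm, x$slice_thickness_mm))
  cat(sprintf("  PSF FWHM %g mm, noise %g HU @ 9 mGy, CTDI_vol %g mGy\n",
              x$psf_fwhm_mm, x$noise_sd_hu, x$ctdi_vol_mgy))
  invisible(x)
}

# Detector-level blur defaults: the photon-counting geometry is modelled
# sharper than the energy-integrating one. FWHM is tied to the detector
# (~2x the 150-mm-FOV pixel pitch of each system), not to the displayed FOV.
.psf_fwhm_defaults <- c(si_pcct = 0.30, eidct = 0.60)

.preset_table <- function() {
  list(
    si_pcct_150 = list(label = "si_pcct_150", fov_mm = 150, matrix_n = 1024L,
                       slice_thickness_mm = 0.42,
                       psf_fwhm_mm = .psf_fwhm_defaults[["si_pcct"]],
                       ctdi_vol_mgy = 8.9, focal_spot_mm = 0.6,
                       tube_kvp = 120),
    si_pcct_50 = list(label = "si_pcct_50", fov_mm = 50, matrix_n = 1024L,
                      slice_thickness_mm = 0.42,
                      psf_fwhm_mm = .psf_fwhm_defaults[["si_pcct"]],
                      ctdi_vol_mgy = 8.9, focal_spot_mm = 0.6,
                      tube_kvp = 120),
    eidct_150 = list(label = "eidct_150", fov_mm = 150, matrix_n = 512L,
                     slice_thickness_mm = 0.63,
                     psf_fwhm_mm = .psf_fwhm_defaults[["eidct"]],
                     ctdi_vol_mgy = 9, focal_spot_mm = 1.2,
                     tube_kvp = 120),
    eidct_50 = list(label = "eidct_50", fov_mm = 50, matrix_n = 512L,
                    slice_thickness_mm = 0.63,
                    psf_fwhm_mm = .psf_fwhm_defaults[["eidct"]],
                    ctdi_vol_mgy = 9, focal_spot_mm = 1.2,
                    tube_kvp = 120)
  )
}

#' Built-in scanner presets
#'
#' Four configurations pairing two detector models with two reconstruction
#' fields of view: a silicon photon-counting geometry (`si_pcct_*`, 1024^2
#' matrix, 0.42 mm slices, 0.6 mm focal spot, 8.9 mGy) and an
#' energy-integrating geometry (`eidct_*`, 512^2 matrix, 0.63 mm slices,
#' 1.2 mm focal spot, 9 mGy), each reconstructed at 150 mm and 50 mm FOV.
#' The PSF FWHM and noise level are effective model parameters (see
#' [system_config()]) and can be overridden after construction.
#'
#' @param name One of `"si_pcct_150"`, `"si_pcct_50"`, `"eidct_150"`,
#'   `"eidct_50"`.
#' @param ... Named overrides passed to [system_config()] (e.g.
#'   `psf_fwhm_mm`, `noise_sd_hu`).
#' @return A `system_config`.
#' @examples
#' preset_config("si_pcct_150")$pixel_mm  # 0.146...
#' @export
preset_config <- function(name, ...) {
  tab <- .preset_table()
  if (length(name) != 1L || !name %in% names(tab)) {
    stop(sprintf("unknown preset %s; valid presets: %s",
                 deparse(substitute(name)),
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  args <- utils::modifyList(tab[[name]], list(...))
  do.call(system_config, args)
}

#' Read or write a system configuration
#'
#' Configurations serialize to YAML (default) or JSON with keys named exactly
#' as the `system_config` fields; lengths are in mm and dose in mGy. The
#' derived `pixel_mm` is written for readability and checked (not trusted) on
#' read.
#'
#' @param cfg A `system_config`.
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   otherwise YAML).
#' @return `write_system_config()` returns `path` invisibly;
#'   `read_system_config()` returns a `system_config`.
#' @export
write_system_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "system_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_system_config
#' @export
read_system_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  x$pixel_mm <- NULL
  do.call(system_config, x)
}
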
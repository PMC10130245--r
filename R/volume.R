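#' 3-D HU image volume
#'
#' Thin container for a 3-D grid of Hounsfield units with voxel spacing and
#' a world-space origin (the center of voxel `[1, 1, 1]`, in mm). The first
#' two array axes are in-plane (x, y); the third is axial (z).
#'
#' @param voxels Numeric 3-D array of HU values.
#' @param spacing_mm Numeric length-3 vector `(dx, dy, dz)`, all > 0.
#' @param origin_mm Numeric length-3 vector, world position of the first
#'   voxel center. Defaults to centering the grid on the world origin.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm, origin_mm = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L) {
    stop("`voxels` must be a non-empty 3-D array", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three strictly positive numbers", call. = FALSE)
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(dim(voxels) - 1) / 2 * spacing_mm
  }
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# World coordinates of voxel centers along one axis (1 = x, 2 = y, 3 = z).
axis_coords <- function(vol, axis) {
  n <- dim(vol$voxels)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 1) * vol$spacing_mm[axis]
}

#' Read or write an image volume as NIfTI
#'
#' Voxel spacing is carried in the NIfTI `pixdim` header field.
#'
#' @param vol An `image_volume`.
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @note A single-slice volume is stored as a 2-D NIfTI image (trailing
#'   singleton dimensions are squeezed), so its axial spacing defaults to
#'   1 mm when read back.
#' @return `read_volume_nifti()` returns an `image_volume`;
#'   `write_volume_nifti()` returns `path` invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  sp <- as.numeric(RNifti::niftiHeader(img)$pixdim)[2:4]
  sp[!is.finite(sp) | sp <= 0] <- 1  # degenerate axes (e.g. single slice)
  image_volume(arr, spacing_mm = sp)
}
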
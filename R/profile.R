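#' Extract an HU line profile from an axial slice
#'
#' Samples HU by bilinear interpolation at uniform steps along a diametral
#' line through `center_mm` at angle `angle` within slice `slice_index`.
#' Signed positions run from `-half_length_mm` to `+half_length_mm`; the
#' direction of positive positions is `(cos(angle), sin(angle))`.
#'
#' @param image An `image_volume`.
#' @param slice_index Axial slice (1-based).
#' @param center_mm World (x, y) of the line center, mm.
#' @param angle Line angle in radians.
#' @param half_length_mm Half length of the line (mm).
#' @param step_mm Sampling step (mm).
#' @return A `line_profile`: list with strictly increasing `position_mm`,
#'   `hu`, and origin/angle metadata.
#' @export
extract_profile <- function(image, slice_index, center_mm, angle,
                            half_length_mm, step_mm) {
  stopifnot(inherits(image, "image_volume"))
  d <- dim(image$voxels)
  if (slice_index < 1L || slice_index > d[3]) {
    stop("out-of-bounds error: slice_index outside volume", call. = FALSE)
  }
  stopifnot(step_mm > 0, half_length_mm > 0, length(center_mm) == 2L)
  nh <- floor(half_length_mm / step_mm)
  pos <- (-nh:nh) * step_mm  # symmetric about the line centre
  xp <- center_mm[1] + pos * cos(angle)
  yp <- center_mm[2] + pos * sin(angle)
  xc <- axis_coords(image, 1L)
  yc <- axis_coords(image, 2L)
  if (min(xp) < xc[1] || max(xp) > xc[length(xc)] ||
      min(yp) < yc[1] || max(yp) > yc[length(yc)]) {
    stop("out-of-bounds error: profile line exits the image", call. = FALSE)
  }
  hu <- pracma::interp2(xc, yc, t(image$voxels[, , slice_index]), xp, yp,
                        method = "linear")
  line_profile(pos, hu, center_mm = center_mm, angle = angle,
               slice_index = slice_index)
}

#' @rdname extract_profile
#' @param position_mm Strictly increasing positions (mm).
#' @param hu HU samples, same length as `position_mm`.
#' @param center_mm,slice_index Metadata (optional).
#' @export
line_profile <- function(position_mm, hu, center_mm = c(NA, NA), angle = NA,
                         slice_index = NA) {
  position_mm <- as.numeric(position_mm)
  hu <- as.numeric(hu)
  if (length(position_mm) != length(hu)) {
    stop("`position_mm` and `hu` must have equal length", call. = FALSE)
  }
  if (length(position_mm) < 1L || any(diff(position_mm) <= 0)) {
    stop("`position_mm` must be strictly increasing", call. = FALSE)
  }
  structure(list(position_mm = position_mm, hu = hu,
                 center_mm = center_mm, angle = angle,
                 slice_index = slice_index),
            class = "line_profile")
}

#' @export
as.data.frame.line_profile <- function(x, ...) {
  data.frame(position_mm = x$position_mm, hu = x$hu)
}

# Prominence of the local maximum at index i of y: height above the higher
# of the two key saddles (lowest point between the peak and the nearest
# higher terrain on each side; the record edge if no higher terrain).
.peak_prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  right <- if (i < length(y)) y[(i + 1L):length(y)] else numeric(0)
  saddle <- function(seg) {
    if (length(seg) == 0L) return(min(h, min(y)))
    higher <- which(seg > h)
    if (length(higher) == 0L) min(seg) else min(seg[(max(higher) + 1L):length(seg)])
  }
  lv <- saddle(left)
  higher_r <- which(right > h)
  rv <- if (length(right) == 0L) {
    min(h, min(y))
  } else if (length(higher_r) == 0L) {
    min(right)
  } else {
    min(right[seq_len(min(higher_r) - 1L)])
  }
  h - max(lv, rv)
}

#' Find local maxima with subpixel refinement
#'
#' Detects interior local maxima whose topographic prominence exceeds
#' `min_prominence_hu` and refines each position and height by the vertex of
#' the parabola through the three samples around the maximum.
#'
#' @param profile A `line_profile` (or anything with `position_mm` and `hu`).
#' @param min_prominence_hu Minimum prominence in HU.
#' @return A data.frame with columns `position_mm`, `height_hu`,
#'   `prominence_hu`, sorted by position; zero rows when no peak qualifies.
#' @export
find_peaks_subpixel <- function(profile, min_prominence_hu = 0) {
  y <- profile$hu
  x <- profile$position_mm
  n <- length(y)
  if (n < 3L) stop("profile must have at least 3 samples", call. = FALSE)
  # interior strict-or-plateau maxima: y[i] >= neighbours, > somewhere
  cand <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                  (y[2:(n - 1)] > y[1:(n - 2)] | y[2:(n - 1)] > y[3:n])) + 1L
  out <- list()
  for (i in cand) {
    prom <- .peak_prominence(y, i)
    if (prom <= min_prominence_hu) next
    yl <- y[i - 1L]; y0 <- y[i]; yr <- y[i + 1L]
    denom <- yl - 2 * y0 + yr
    if (denom < 0) {
      p <- 0.5 * (yl - yr) / denom
      p <- max(-0.5, min(0.5, p))
      step <- (x[i + 1L] - x[i - 1L]) / 2
      pos <- x[i] + p * step
      hgt <- y0 - 0.25 * (yl - yr) * p
    } else {
      pos <- x[i]; hgt <- y0
    }
    out[[length(out) + 1L]] <- c(pos, hgt, prom)
  }
  if (length(out) == 0L) {
    return(data.frame(position_mm = numeric(0), height_hu = numeric(0),
                      prominence_hu = numeric(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(position_mm = m[, 1], height_hu = m[, 2],
                   prominence_hu = m[, 3])
  df[order(df$position_mm), , drop = FALSE]
}
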
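#' Estimate a stent ring centroid
#'
#' Intensity-weighted centroid of the voxels brighter than halfway between
#' the local background (median of the search box) and the local maximum,
#' iterated once from `center_hint_mm`.
#'
#' @param image An `image_volume`.
#' @param slice_index Axial slice.
#' @param center_hint_mm Approximate (x, y) of the ring center, mm.
#' @param search_radius_mm Half-width of the square search box, mm.
#' @return Refined (x, y) center in mm.
#' @export
estimate_ring_centroid <- function(image, slice_index, center_hint_mm,
                                   search_radius_mm) {
  xc <- axis_coords(image, 1L)
  yc <- axis_coords(image, 2L)
  sl <- image$voxels[, , slice_index]
  ctr <- as.numeric(center_hint_mm)
  for (pass in 1:2) {
    ix <- which(abs(xc - ctr[1]) <= search_radius_mm)
    iy <- which(abs(yc - ctr[2]) <= search_radius_mm)
    if (length(ix) < 3L || length(iy) < 3L) {
      stop("out-of-bounds error: centroid search box outside image",
           call. = FALSE)
    }
    box <- sl[ix, iy]
    bg <- stats::median(box)
    thr <- bg + 0.5 * (max(box) - bg)
    w <- pmax(box - bg, 0)
    w[box < thr] <- 0
    if (sum(w) <= 0) {
      stop("measurement-failure error: no voxels above centroid threshold",
           call. = FALSE)
    }
    wx <- rowSums(w); wy <- colSums(w)
    ctr <- c(sum(wx * xc[ix]) / sum(wx), sum(wy * yc[iy]) / sum(wy))
  }
  ctr
}

# Longest half-length from `center` along +/- direction `angle` that stays
# strictly inside the in-plane extent of the volume.
.max_half_length <- function(image, center_mm, angle) {
  xc <- axis_coords(image, 1L)
  yc <- axis_coords(image, 2L)
  u <- c(cos(angle), sin(angle))
  lim <- function(lo, hi, c0, d) {
    if (abs(d) < 1e-12) return(Inf)
    max((lo - c0) / d, (hi - c0) / d)  # one of the two is positive
  }
  bound <- function(sgn) {
    min(lim(xc[1], xc[length(xc)], center_mm[1], sgn * u[1]),
        lim(yc[1], yc[length(yc)], center_mm[2], sgn * u[2]))
  }
  0.999 * min(bound(1), bound(-1))
}

# Pick, among detected peaks, the one whose |position| is closest to
# `target_r` within `window`; NA when none qualifies.
.pick_peak <- function(peaks, target_r, window) {
  if (nrow(peaks) == 0L) return(NA_integer_)
  d <- abs(abs(peaks$position_mm) - target_r)
  i <- which.min(d)
  if (d[i] <= window) i else NA_integer_
}

#' Measure stent diameter by the peak-to-peak method
#'
#' On each selected axial slice, HU profiles are taken along equally spaced
#' diametral lines through the (optionally re-estimated) ring centroid; the
#' diameter of one line is the distance between the two opposing strut-peak
#' positions (subpixel-refined). When `expected_diameter_mm` is given, the
#' peak nearest the expected radius (within `radius_window_mm`) is used on
#' each side - required when a second stent shares the lumen; otherwise the
#' outermost peak on each side is used. Lines on which a side has no
#' qualifying peak are excluded; more than 50% exclusions abort.
#'
#' @param image An `image_volume`.
#' @param center_hint_mm Approximate ring center (x, y), mm.
#' @param slice_indices Axial slices to measure (the replicate locations).
#' @param n_angles Number of diametral lines per slice.
#' @param angles_deg Optional explicit line angles (degrees); overrides
#'   `n_angles`. An arc `c(lo, hi)` of length 2 is expanded to `n_angles`
#'   equally spaced lines.
#' @param expected_diameter_mm Optional prior diameter for peak selection.
#' @param radius_window_mm Half-width of the peak-selection window around
#'   the expected radius.
#' @param step_mm Profile sampling step; default `pixel / 4`.
#' @param min_prominence_hu Peak prominence threshold.
#' @param refine_center Re-estimate the centroid per slice
#'   ([estimate_ring_centroid()]); disable when a neighbouring stent would
#'   bias it.
#' @return A list with `mean`, `sd`, `n`, per-line tibble `lines`
#'   (slice, angle_deg, diameter_mm), per-slice means `per_location`, and
#'   `n_excluded`.
#' @export
measure_diameter <- function(image, center_hint_mm, slice_indices,
                             n_angles = 8L, angles_deg = NULL,
                             expected_diameter_mm = NULL,
                             radius_window_mm = 0.45,
                             step_mm = NULL, min_prominence_hu = 150,
                             refine_center = TRUE) {
  stopifnot(inherits(image, "image_volume"))
  if (is.null(step_mm)) step_mm <- image$spacing_mm[1] / 4
  angles <- .expand_angles(angles_deg, n_angles, diametral = TRUE)
  rows <- list()
  n_excluded <- 0L
  for (sl in slice_indices) {
    ctr <- if (refine_center) {
      sr <- if (is.null(expected_diameter_mm)) 6 else expected_diameter_mm / 2 + 1.5
      estimate_ring_centroid(image, sl, center_hint_mm, sr)
    } else as.numeric(center_hint_mm)
    for (a in angles) {
      want <- if (is.null(expected_diameter_mm)) 8 else expected_diameter_mm / 2 + 2.5
      hl <- min(want, .max_half_length(image, ctr, a))
      prof <- extract_profile(image, sl, ctr, a, hl, step_mm)
      pk <- find_peaks_subpixel(prof, min_prominence_hu)
      left <- pk[pk$position_mm < 0, , drop = FALSE]
      right <- pk[pk$position_mm > 0, , drop = FALSE]
      if (is.null(expected_diameter_mm)) {
        li <- if (nrow(left)) which.min(left$position_mm) else NA_integer_
        ri <- if (nrow(right)) which.max(right$position_mm) else NA_integer_
      } else {
        r_exp <- expected_diameter_mm / 2
        li <- .pick_peak(left, r_exp, radius_window_mm)
        ri <- .pick_peak(right, r_exp, radius_window_mm)
      }
      if (is.na(li) || is.na(ri)) {
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slice = sl, angle_deg = a * 180 / pi,
        diameter_mm = right$position_mm[ri] - left$position_mm[li])
    }
  }
  n_total <- length(slice_indices) * length(angles)
  if (n_excluded > 0.5 * n_total) {
    stop(sprintf(
      "measurement-failure error: %d of %d diametral lines had no usable peak pair",
      n_excluded, n_total), call. = FALSE)
  }
  lines <- do.call(rbind, rows)
  per_loc <- stats::aggregate(diameter_mm ~ slice, data = lines, FUN = mean)
  list(mean = mean(lines$diameter_mm), sd = stats::sd(lines$diameter_mm),
       n = nrow(lines), lines = lines,
       per_location = tibble::as_tibble(per_loc), n_excluded = n_excluded)
}

.expand_angles <- function(angles_deg, n_angles, diametral = TRUE) {
  if (is.null(angles_deg)) {
    span <- if (diametral) pi else 2 * pi
    return(seq(0, span, length.out = n_angles + 1L)[seq_len(n_angles)])
  }
  if (length(angles_deg) == 2L && n_angles > 2L) {
    angles_deg <- seq(angles_deg[1], angles_deg[2], length.out = n_angles)
  }
  angles_deg * pi / 180
}

#' Mean absolute error of diameter measurements
#'
#' @param measured Numeric vector of measured diameters (mm).
#' @param true_d Ground-truth diameter (mm).
#' @return Mean of `|measured - true_d|`, mm.
#' @export
mean_abs_error <- function(measured, true_d) {
  measured <- as.numeric(measured)
  if (length(measured) < 1L || any(!is.finite(measured))) {
    stop("`measured` must be a non-empty finite vector", call. = FALSE)
  }
  stopifnot(is.finite(true_d))
  mean(abs(measured - true_d))
}

#' Blooming percentage from inner and outer areas
#'
#' `(A_outer - A_inner) / A_outer * 100`: the apparent strut ring's share of
#' the disk it encloses, the standard half-maximum blooming surrogate.
#'
#' @param a_inner_mm2,a_outer_mm2 Inner and outer areas (mm^2), with
#'   `0 < a_inner <= a_outer`.
#' @return Blooming percentage in `[0, 100]`.
#' @examples
#' blooming_from_areas(80, 100)  # 20
#' @export
blooming_from_areas <- function(a_inner_mm2, a_outer_mm2) {
  if (any(!is.finite(a_inner_mm2)) || any(!is.finite(a_outer_mm2)) ||
      any(a_outer_mm2 <= 0) || any(a_inner_mm2 < 0)) {
    stop("areas must be finite and positive", call. = FALSE)
  }
  if (any(a_inner_mm2 > a_outer_mm2 + 1e-12)) {
    stop("`a_inner_mm2` must not exceed `a_outer_mm2`", call. = FALSE)
  }
  pmin(100, pmax(0, (a_outer_mm2 - a_inner_mm2) / a_outer_mm2 * 100))
}

#' Measure strut blooming from half-maximum radii
#'
#' On each slice, radial HU profiles from the centroid locate the strut
#' peak at every angle together with its inner and outer half-maximum
#' crossing radii (half maximum relative to the local background, the
#' median HU in a lumen window just inside the strut). Per slice,
#' `r_inner`/`r_outer` are the angular means of the crossings,
#' `A = pi r^2`, and blooming is [blooming_from_areas()] of the two areas.
#'
#' @inheritParams measure_diameter
#' @param expected_diameter_mm Prior ring diameter (required: anchors peak
#'   selection).
#' @param angles_deg Optional radial angles (degrees, full circle); an arc
#'   `c(lo, hi)` is expanded to `n_angles` lines.
#' @param bg_window_mm Radial window inside the strut used for the local
#'   background, as distances inward from the peak `c(near, far)`.
#' @return A list with `mean`, `sd` (blooming %, over slices), per-slice
#'   tibble `per_location` (r_inner/r_outer/areas/blooming), per-angle
#'   tibble `rays`, and `n_excluded`.
#' @export
measure_blooming <- function(image, center_hint_mm, slice_indices,
                             expected_diameter_mm,
                             n_angles = 8L, angles_deg = NULL,
                             radius_window_mm = 0.45, step_mm = NULL,
                             min_prominence_hu = 150,
                             bg_window_mm = c(0.6, 1.2),
                             refine_center = TRUE) {
  stopifnot(inherits(image, "image_volume"), is.finite(expected_diameter_mm))
  if (is.null(step_mm)) step_mm <- image$spacing_mm[1] / 4
  angles <- .expand_angles(angles_deg, n_angles, diametral = FALSE)
  r_exp <- expected_diameter_mm / 2
  rays <- list()
  n_excluded <- 0L
  for (sl in slice_indices) {
    ctr <- if (refine_center) {
      estimate_ring_centroid(image, sl, center_hint_mm, r_exp + 1.5)
    } else as.numeric(center_hint_mm)
    for (a in angles) {
      hl <- min(r_exp + 2.5, .max_half_length(image, ctr, a))
      prof <- extract_profile(image, sl, ctr, a, hl, step_mm)
      keep <- prof$position_mm >= 0
      radial <- line_profile(prof$position_mm[keep], prof$hu[keep])
      pk <- find_peaks_subpixel(radial, min_prominence_hu)
      pi_ <- .pick_peak(pk, r_exp, radius_window_mm)
      if (is.na(pi_)) { n_excluded <- n_excluded + 1L; next }
      r_peak <- pk$position_mm[pi_]
      h_peak <- pk$height_hu[pi_]
      in_bg <- radial$position_mm >= r_peak - bg_window_mm[2] &
        radial$position_mm <= r_peak - bg_window_mm[1]
      if (!any(in_bg)) { n_excluded <- n_excluded + 1L; next }
      bg <- stats::median(radial$hu[in_bg])
      level <- bg + 0.5 * (h_peak - bg)
      cross <- .half_max_crossings(radial$position_mm, radial$hu, r_peak, level)
      if (any(is.na(cross))) { n_excluded <- n_excluded + 1L; next }
      rays[[length(rays) + 1L]] <- tibble::tibble(
        slice = sl, angle_deg = a * 180 / pi, r_peak_mm = r_peak,
        peak_hu = h_peak, background_hu = bg,
        r_inner_mm = cross[1], r_outer_mm = cross[2])
    }
  }
  n_total <- length(slice_indices) * length(angles)
  if (length(rays) == 0L) {
    stop("measurement-failure error: no radial ray yielded half-maximum crossings",
         call. = FALSE)
  }
  rays <- do.call(rbind, rays)
  per_loc <- do.call(rbind, lapply(split(rays, rays$slice), function(d) {
    r_i <- mean(d$r_inner_mm); r_o <- mean(d$r_outer_mm)
    tibble::tibble(slice = d$slice[1], r_inner_mm = r_i, r_outer_mm = r_o,
                   inner_area_mm2 = pi * r_i^2, outer_area_mm2 = pi * r_o^2,
                   blooming_pct = blooming_from_areas(pi * r_i^2, pi * r_o^2))
  }))
  list(mean = mean(per_loc$blooming_pct), sd = stats::sd(per_loc$blooming_pct),
       per_location = tibble::as_tibble(per_loc), rays = tibble::as_tibble(rays),
       n_excluded = n_excluded)
}

# Inner and outer radii where the profile crosses `level` around the peak
# at r_peak; linear interpolation between samples; NA when not bracketed.
.half_max_crossings <- function(r, y, r_peak, level) {
  i0 <- which.min(abs(r - r_peak))
  inner <- NA_real_
  if (i0 >= 2L) for (j in seq(i0, 2L)) {
    if (y[j - 1L] <= level && y[j] > level) {
      f <- (level - y[j - 1L]) / (y[j] - y[j - 1L])
      inner <- r[j - 1L] + f * (r[j] - r[j - 1L])
      break
    }
  }
  outer_ <- NA_real_
  if (i0 < length(r)) {
    for (j in seq(i0, length(r) - 1L)) {
      if (y[j] > level && y[j + 1L] <= level) {
        f <- (y[j] - level) / (y[j] - y[j + 1L])
        outer_ <- r[j] + f * (r[j + 1L] - r[j])
        break
      }
    }
  }
  c(inner, outer_)
}

#' Inter-stent distinction index
#'
#' `(peak - trough) / (peak - minimum) * 100`, clamped to `[0, 100]`: how
#' deeply the HU profile dips between two adjacent strut peaks (`trough`),
#' relative to the peak height above the image background (`minimum`).
#' 100 means the gap falls all the way to background; 0 means the struts
#' have merged into one ridge.
#'
#' @param peak_hu Mean height of the two adjacent strut peaks (HU).
#' @param trough_hu Minimum HU between the peaks.
#' @param minimum_hu Background reference HU far from both stents.
#' @return Distinction percentage in `[0, 100]`.
#' @examples
#' distinction_index(1000, 10, 10)    # 100
#' distinction_index(1000, 1000, 10)  # 0
#' @export
distinction_index <- function(peak_hu, trough_hu, minimum_hu) {
  if (any(!is.finite(c(peak_hu, trough_hu, minimum_hu)))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(peak_hu - minimum_hu <= 0)) {
    stop("`peak_hu` must exceed `minimum_hu`", call. = FALSE)
  }
  pmin(100, pmax(0, (peak_hu - trough_hu) / (peak_hu - minimum_hu) * 100))
}

#' Measure inter-stent distinction
#'
#' For a lumen holding two intertwined stents, extracts an HU profile along
#' the inter-stent gap axis crossing one strut of each stent, and scores how
#' separable the two struts are: `peak` is the mean of the two adjacent
#' strut-peak heights, `trough` the minimum HU between them, and `minimum`
#' the background HU in an agar annulus far from the vessel
#' (`background_radii_mm` from the vessel center). See
#' [distinction_index()]. A location where the two struts have merged into
#' a single peak scores 0 and is flagged.
#'
#' @param image An `image_volume`.
#' @param center1_mm,center2_mm Ring centers (x, y) of the two stents, mm.
#' @param diameter1_mm,diameter2_mm Expected ring diameters, mm.
#' @param slice_indices Axial slices (replicate locations).
#' @param gap_angle Direction (radians) from the vessel center toward the
#'   gap; default: the direction from stent 1's center to stent 2's.
#' @param background_radii_mm Radii `c(lo, hi)` of the background annulus
#'   around the vessel center; default 2-3 times the larger stent radius.
#' @param step_mm Profile sampling step; default `pixel / 4`.
#' @param min_prominence_hu Peak prominence threshold.
#' @param peak_window_mm Search window around each strut's expected position.
#' @return A list with `mean`, `sd` (distinction %, over slices), per-slice
#'   tibble `per_location` (peak/trough/minimum/distinction/merged flag).
#' @export
measure_distinction <- function(image, center1_mm, center2_mm,
                                diameter1_mm, diameter2_mm, slice_indices,
                                gap_angle = NULL, background_radii_mm = NULL,
                                step_mm = NULL, min_prominence_hu = 150,
                                peak_window_mm = 0.5) {
  stopifnot(inherits(image, "image_volume"))
  if (is.null(step_mm)) step_mm <- image$spacing_mm[1] / 4
  c1 <- as.numeric(center1_mm); c2 <- as.numeric(center2_mm)
  vessel_ctr <- (c1 + c2) / 2
  if (is.null(gap_angle)) gap_angle <- atan2(c2[2] - c1[2], c2[1] - c1[1])
  u <- c(cos(gap_angle), sin(gap_angle))
  r1 <- diameter1_mm / 2; r2 <- diameter2_mm / 2
  if (is.null(background_radii_mm)) background_radii_mm <- c(2, 3) * max(r1, r2)
  # expected strut positions on the gap side, as signed distances along u
  # from the profile center (midpoint of the two expected struts)
  p1 <- c1 + r1 * u
  p2 <- c2 + r2 * u
  mid <- (p1 + p2) / 2
  t1 <- sum((p1 - mid) * u)
  t2 <- sum((p2 - mid) * u)

  xc <- axis_coords(image, 1L)
  yc <- axis_coords(image, 2L)
  rr <- sqrt(outer((xc - vessel_ctr[1])^2, (yc - vessel_ctr[2])^2, "+"))
  bg_mask <- rr >= background_radii_mm[1] & rr <= background_radii_mm[2]
  if (!any(bg_mask)) {
    stop("out-of-bounds error: background annulus outside the image",
         call. = FALSE)
  }

  rows <- list()
  for (sl in slice_indices) {
    minimum <- mean(image$voxels[, , sl][bg_mask])
    hl <- min(abs(t2 - t1) / 2 + 2, .max_half_length(image, mid, gap_angle))
    prof <- extract_profile(image, sl, mid, gap_angle, hl, step_mm)
    pk <- find_peaks_subpixel(prof, min_prominence_hu)
    i1 <- .pick_signed_peak(pk, t1, peak_window_mm)
    i2 <- .pick_signed_peak(pk, t2, peak_window_mm)
    merged <- is.na(i1) || is.na(i2) || i1 == i2
    if (merged) {
      peak <- if (nrow(pk)) max(pk$height_hu) else max(prof$hu)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slice = sl, peak_hu = peak, trough_hu = peak, minimum_hu = minimum,
        distinction_pct = 0, merged = TRUE)
      next
    }
    pos <- sort(c(pk$position_mm[i1], pk$position_mm[i2]))
    between <- prof$position_mm > pos[1] & prof$position_mm < pos[2]
    trough <- if (any(between)) min(prof$hu[between]) else
      min(pk$height_hu[c(i1, i2)])
    peak <- mean(pk$height_hu[c(i1, i2)])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      slice = sl, peak_hu = peak, trough_hu = min(trough, peak),
      minimum_hu = minimum,
      distinction_pct = distinction_index(peak, min(trough, peak), minimum),
      merged = FALSE)
  }
  per_loc <- do.call(rbind, rows)
  list(mean = mean(per_loc$distinction_pct),
       sd = stats::sd(per_loc$distinction_pct),
       per_location = tibble::as_tibble(per_loc))
}

.pick_signed_peak <- function(peaks, target, window) {
  if (nrow(peaks) == 0L) return(NA_integer_)
  d <- abs(peaks$position_mm - target)
  i <- which.min(d)
  if (d[i] <= window) i else NA_integer_
}
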
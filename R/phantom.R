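#' Stent geometry specification
#'
#' A stent is modelled as a thin continuous annulus: in every axial slice a
#' ring of metal of radial thickness `strut_thickness_mm` centred at radius
#' `diameter_mm / 2`. `diameter_mm` is the strut-ring centreline diameter,
#' i.e. the ground-truth diameter that measurement should recover.
#'
#' @param diameter_mm Strut-ring centreline diameter (mm).
#' @param strut_thickness_mm Radial strut thickness (mm); default 0.15 mm,
#'   typical of a balloon-expandable covered stent. The radiolucent polymer
#'   cover is not modelled.
#' @param center_offset_mm In-plane (x, y) offset of the stent axis from the
#'   vessel axis, used to build an intertwined pair.
#' @param axial_extent_mm Length of the stent along z; `Inf` spans the whole
#'   volume.
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(diameter_mm, strut_thickness_mm = 0.15,
                       center_offset_mm = c(0, 0), axial_extent_mm = Inf) {
  if (!is.finite(strut_thickness_mm) || strut_thickness_mm <= 0) {
    stop("`strut_thickness_mm` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(diameter_mm) || diameter_mm <= 2 * strut_thickness_mm) {
    stop("`diameter_mm` must exceed twice the strut thickness", call. = FALSE)
  }
  center_offset_mm <- as.numeric(center_offset_mm)
  stopifnot(length(center_offset_mm) == 2L, all(is.finite(center_offset_mm)))
  structure(list(diameter_mm = diameter_mm,
                 strut_thickness_mm = strut_thickness_mm,
                 center_offset_mm = center_offset_mm,
                 axial_extent_mm = axial_extent_mm),
            class = "stent_spec")
}

#' Stented-vessel phantom specification
#'
#' Describes the geometry and HU assignments of the simulated specimen: a
#' soft-tissue-equivalent (agar) cylinder holding a centrally placed,
#' contrast-filled artery that carries one or two metal stents. Default HU
#' values follow standard 120-kVp conventions: 2% agar-water at 10 HU,
#' 15 mg/mL iodinated contrast at 390 HU (about 26 HU per mg/mL), vessel
#' wall at 50 HU, and stainless-steel struts at 8000 HU before blurring.
#'
#' @param stents A `stent_spec` or list of 1-2 of them.
#' @param vessel_lumen_diameter_mm Inner diameter of the contrast-filled
#'   lumen (mm); must exceed the outer extent of every stent.
#' @param wall_thickness_mm Vessel wall thickness (mm).
#' @param cylinder_diameter_mm Diameter of the surrounding agar cylinder (mm).
#' @param background_hu,lumen_hu,wall_hu,metal_hu Material HU values; must
#'   satisfy `metal_hu > lumen_hu > background_hu`.
#' @param label Optional specimen label.
#' @return An object of class `phantom_spec`.
#' @seealso [phantom_preset()] for the three built-in specimens.
#' @export
phantom_spec <- function(stents, vessel_lumen_diameter_mm,
                         wall_thickness_mm = 1,
                         cylinder_diameter_mm = 200,
                         background_hu = 10, lumen_hu = 390, wall_hu = 50,
                         metal_hu = 8000, label = "phantom") {
  if (inherits(stents, "stent_spec")) stents <- list(stents)
  if (!is.list(stents) || length(stents) < 1L || length(stents) > 2L ||
      !all(vapply(stents, inherits, logical(1), "stent_spec"))) {
    stop("`stents` must be a list of 1 or 2 stent_spec objects", call. = FALSE)
  }
  if (!(metal_hu > lumen_hu && lumen_hu > background_hu)) {
    stop("HU ordering violated: need metal_hu > lumen_hu > background_hu",
         call. = FALSE)
  }
  lumen_r <- vessel_lumen_diameter_mm / 2
  for (s in stents) {
    reach <- sqrt(sum(s$center_offset_mm^2)) +
      s$diameter_mm / 2 + s$strut_thickness_mm / 2
    if (reach >= lumen_r) {
      stop(sprintf(
        "geometry error: stent (outer reach %.2f mm) does not fit inside the %.2f mm lumen",
        reach, vessel_lumen_diameter_mm), call. = FALSE)
    }
  }
  structure(list(stents = stents,
                 vessel_lumen_diameter_mm = vessel_lumen_diameter_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 cylinder_diameter_mm = cylinder_diameter_mm,
                 background_hu = background_hu, lumen_hu = lumen_hu,
                 wall_hu = wall_hu, metal_hu = metal_hu, label = label),
            class = "phantom_spec")
}

#' Built-in specimen phantoms
#'
#' Three stented-artery specimens with mammography-calibrated ground-truth
#' diameters: `"carotid"` (single 5.5 mm stent), `"iliac"` (single 8.5 mm
#' stent) and `"femoral"` (two intertwined stents, 7 mm and 5.8 mm, whose
#' axes are offset by 1.4 mm so that on the inter-stent axis the adjacent
#' struts sit 0.8 mm apart - the fixture for inter-stent distinction).
#'
#' @param name One of `"carotid"`, `"femoral"`, `"iliac"`.
#' @return A `phantom_spec`. For `"femoral"` the attribute
#'   `"measure_arcs"` records, per stent, diametral/radial measurement arcs
#'   (degrees) that avoid the crossing points of the two rings, plus the
#'   direction of the inter-stent gap.
#' @export
phantom_preset <- function(name) {
  switch(match.arg(name, c("carotid", "femoral", "iliac")),
    carotid = phantom_spec(stent_spec(5.5), vessel_lumen_diameter_mm = 7.5,
                           label = "carotid"),
    iliac = phantom_spec(stent_spec(8.5), vessel_lumen_diameter_mm = 10.5,
                         label = "iliac"),
    femoral = {
      sp <- phantom_spec(
        list(stent_spec(7.0, center_offset_mm = c(-0.7, 0)),
             stent_spec(5.8, center_offset_mm = c(0.7, 0))),
        vessel_lumen_diameter_mm = 10.0, label = "femoral")
      # Arcs (degrees) along which each ring is well separated from the
      # other ring's crossings; derived from the circle-circle geometry.
      attr(sp, "measure_arcs") <- list(
        list(diametral_deg = c(70, 110), radial_deg = c(135, 225)),
        list(diametral_deg = c(-20, 20), radial_deg = c(135, 225)))
      attr(sp, "gap_direction_deg") <- 0  # gap lies on the +x axis
      sp
    })
}

#' Rasterize a phantom to a ground-truth HU volume
#'
#' Samples the phantom geometry on a fine ("supersampled") grid: each voxel
#' takes the HU of the material whose region contains its center. The grid
#' is centred on the vessel axis. Geometry is axially uniform except for
#' stents of finite `axial_extent_mm`.
#'
#' @param spec A `phantom_spec`.
#' @param supersample_spacing_mm In-plane sampling pitch (mm); must be
#'   <= 0.02 so the finest strut is oversampled.
#' @param extent_mm In-plane extent of the rasterized region (mm). Defaults
#'   to the vessel outer diameter plus a 6 mm agar margin. (The full 200 mm
#'   cylinder never needs rasterizing: all measurements live near the
#'   vessel.)
#' @param n_slices Number of axial slices.
#' @param slice_spacing_mm Axial spacing between slice centers (mm).
#' @return An `image_volume` of ground-truth HU.
#' @export
rasterize_phantom <- function(spec, supersample_spacing_mm,
                              extent_mm = NULL, n_slices = 3L,
                              slice_spacing_mm = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.finite(supersample_spacing_mm) || supersample_spacing_mm <= 0 ||
      supersample_spacing_mm > 0.02) {
    stop("`supersample_spacing_mm` must be in (0, 0.02] mm to oversample the strut",
         call. = FALSE)
  }
  if (is.null(extent_mm)) {
    extent_mm <- spec$vessel_lumen_diameter_mm + 2 * spec$wall_thickness_mm + 6
  }
  n <- max(2L, as.integer(round(extent_mm / supersample_spacing_mm)))
  dx <- supersample_spacing_mm
  xc <- (seq_len(n) - (n + 1) / 2) * dx
  zc <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_spacing_mm

  r2 <- outer(xc^2, xc^2, "+")
  base <- matrix(ifelse(r2 <= (spec$cylinder_diameter_mm / 2)^2,
                        spec$background_hu, -1000), n, n)
  lumen_r <- spec$vessel_lumen_diameter_mm / 2
  base[r2 <= (lumen_r + spec$wall_thickness_mm)^2] <- spec$wall_hu
  base[r2 <= lumen_r^2] <- spec$lumen_hu

  stent_masks <- lapply(spec$stents, function(s) {
    rs <- sqrt(outer((xc - s$center_offset_mm[1])^2,
                     (xc - s$center_offset_mm[2])^2, "+"))
    abs(rs - s$diameter_mm / 2) <= s$strut_thickness_mm / 2
  })

  vox <- array(NA_real_, c(n, n, n_slices))
  all_infinite <- all(vapply(spec$stents,
                             function(s) is.infinite(s$axial_extent_mm),
                             logical(1)))
  slice_full <- base
  for (i in seq_along(spec$stents)) slice_full[stent_masks[[i]]] <- spec$metal_hu
  for (k in seq_len(n_slices)) {
    if (all_infinite) {
      vox[, , k] <- slice_full
    } else {
      sl <- base
      for (i in seq_along(spec$stents)) {
        if (abs(zc[k]) <= spec$stents[[i]]$axial_extent_mm / 2) {
          sl[stent_masks[[i]]] <- spec$metal_hu
        }
      }
      vox[, , k] <- sl
    }
  }
  image_volume(vox, spacing_mm = c(dx, dx, slice_spacing_mm),
               origin_mm = c(xc[1], xc[1], zc[1]))
}
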
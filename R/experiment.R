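#' Experiment configuration
#'
#' Assembles the full in-silico study design: which phantoms are imaged
#' under which system configurations, how many replicate locations (axial
#' slices) and diametral lines feed each measurement, and how the reader
#' study is simulated. Defaults reproduce the reference design: carotid
#' (5.5 mm), intertwined femoral pair (7 and 5.8 mm) and iliac (8.5 mm)
#' specimens under the four presets of [preset_config()], three locations
#' per stent.
#'
#' Per-volume noise seeds derive from one master seed by a counter scheme:
#' `seed = master_seed * 1000 + volume_index` (volumes enumerated phantom-
#' major, system-minor); reader-simulation seeds use
#' `master_seed * 1000 + 900 + metric_index`.
#'
#' @param systems Named list of `system_config` objects (default: all four
#'   presets).
#' @param phantoms Named list of `phantom_spec` objects (default: the three
#'   specimens from [phantom_preset()]).
#' @param n_locations Axial replicate locations per stent.
#' @param n_angles Diametral/radial lines per location.
#' @param master_seed Master seed (small positive integer).
#' @param noise Simulate quantum noise (`FALSE` gives noiseless volumes).
#' @param reader List of reader-simulation parameters: `n_items` (image
#'   presentations per system and metric), `cut_points`, `noise_sd`
#'   (perceptual), `item_sd` (between-presentation), `reader_bias`.
#' @param out_dir Optional output directory for [run_experiment()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(systems = NULL, phantoms = NULL,
                              n_locations = 3L, n_angles = 8L,
                              master_seed = 1L, noise = TRUE,
                              reader = list(), out_dir = NULL) {
  if (is.null(systems)) {
    nm <- c("si_pcct_150", "si_pcct_50", "eidct_150", "eidct_50")
    systems <- stats::setNames(lapply(nm, preset_config), nm)
  }
  if (is.null(phantoms)) {
    nm <- c("carotid", "femoral", "iliac")
    phantoms <- stats::setNames(lapply(nm, phantom_preset), nm)
  }
  stopifnot(all(vapply(systems, inherits, logical(1), "system_config")),
            all(vapply(phantoms, inherits, logical(1), "phantom_spec")),
            n_locations >= 1L, n_angles >= 2L,
            is.finite(master_seed), master_seed == round(master_seed))
  reader <- utils::modifyList(
    list(n_items = 8L, cut_points = c(-1.5, -0.5, 0.5, 1.5),
         noise_sd = 1.3, item_sd = 0.3, reader_bias = c(0, 0.4),
         n_sessions = 2L),
    reader)
  structure(list(systems = systems, phantoms = phantoms,
                 n_locations = as.integer(n_locations),
                 n_angles = as.integer(n_angles),
                 master_seed = as.integer(master_seed),
                 noise = isTRUE(noise), reader = reader, out_dir = out_dir),
            class = "experiment_config")
}

#' Simulate the noiseless imaging set of an experiment
#'
#' Rasterizes every phantom at a pitch matched to each system
#' ([fine_spacing()]) and applies the deterministic part of the degradation
#' chain (PSF, slice averaging, binning). Noise is added later, per seed,
#' by [measure_experiment()], so the expensive rendering is done once.
#'
#' @param cfg An `experiment_config`.
#' @return A list of entries `phantom|system`, each holding `phantom`,
#'   `system` (names), `spec`, `config` and the clean `volume`.
#' @export
simulate_volumes <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set <- list()
  for (pn in names(cfg$phantoms)) {
    spec <- cfg$phantoms[[pn]]
    extent <- .phantom_extent(spec)
    for (sn in names(cfg$systems)) {
      sys <- cfg$systems[[sn]]
      truth <- rasterize_phantom(spec, fine_spacing(sys), extent_mm = extent,
                                 n_slices = cfg$n_locations,
                                 slice_spacing_mm = sys$slice_thickness_mm)
      vol <- apply_system(truth, sys, add_noise = FALSE)
      set[[paste(pn, sn, sep = "|")]] <-
        list(phantom = pn, system = sn, spec = spec, config = sys,
             volume = vol)
    }
  }
  set
}

# Enough agar to host the distinction background annulus (3x the largest
# stent radius) when two stents are present; a 6 mm margin otherwise.
.phantom_extent <- function(spec) {
  base <- spec$vessel_lumen_diameter_mm + 2 * spec$wall_thickness_mm + 6
  if (length(spec$stents) < 2L) return(base)
  r_max <- max(vapply(spec$stents, function(s) s$diameter_mm / 2, numeric(1)))
  max(base, 2 * (3 * r_max + 0.5))
}

#' Run all stent measurements on an imaging set
#'
#' Adds per-volume quantum noise (seeds derived from `master_seed` by the
#' counter scheme of [experiment_config()]) and measures, for every stent
#' and location: diameter (peak-to-peak), absolute diameter error vs the
#' ground truth, blooming, and - for double-stent phantoms - inter-stent
#' distinction.
#'
#' @param set Output of [simulate_volumes()].
#' @param cfg The `experiment_config` used to build `set`.
#' @param master_seed Override of `cfg$master_seed`.
#' @return A list: `measurements` (tidy per-location tibble with columns
#'   metric, fov, system, stent, location, value), `detail` (per-line /
#'   per-ray tibble), and `volumes` (the noisy volumes, named as `set`).
#' @export
measure_experiment <- function(set, cfg, master_seed = cfg$master_seed) {
  rows <- list()
  detail <- list()
  noisy <- list()
  idx <- 0L
  for (entry in set) {
    idx <- idx + 1L
    sys <- entry$config
    spec <- entry$spec
    vol <- entry$volume
    if (cfg$noise) {
      sd_eff <- sys$noise_sd_hu * sqrt(9 / sys$ctdi_vol_mgy)
      vol <- add_hu_noise(vol, sd_eff, seed = master_seed * 1000 + idx)
    }
    noisy[[paste(entry$phantom, entry$system, sep = "|")]] <- vol
    fov <- as.character(sys$fov_mm)
    family <- sub("_[0-9]+$", "", sys$label)
    arcs <- attr(spec, "measure_arcs")
    slices <- seq_len(dim(vol$voxels)[3])
    single <- length(spec$stents) == 1L

    for (i in seq_along(spec$stents)) {
      st <- spec$stents[[i]]
      stent_id <- paste(entry$phantom, i, sep = "_")
      md <- measure_diameter(
        vol, st$center_offset_mm, slices, n_angles = cfg$n_angles,
        angles_deg = if (!single) arcs[[i]]$diametral_deg,
        expected_diameter_mm = st$diameter_mm, refine_center = single)
      mb <- measure_blooming(
        vol, st$center_offset_mm, slices,
        expected_diameter_mm = st$diameter_mm, n_angles = cfg$n_angles,
        angles_deg = if (!single) arcs[[i]]$radial_deg,
        refine_center = single)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "diameter_mm", fov = fov, system = family,
        stent = stent_id, location = md$per_location$slice,
        value = md$per_location$diameter_mm)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "diameter_abs_error_mm", fov = fov, system = family,
        stent = stent_id, location = md$per_location$slice,
        value = abs(md$per_location$diameter_mm - st$diameter_mm))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "blooming_pct", fov = fov, system = family,
        stent = stent_id, location = mb$per_location$slice,
        value = mb$per_location$blooming_pct)
      detail[[length(detail) + 1L]] <- tibble::tibble(
        metric = "diameter_mm", fov = fov, system = family,
        stent = stent_id, slice = md$lines$slice,
        angle_deg = md$lines$angle_deg, value = md$lines$diameter_mm)
      detail[[length(detail) + 1L]] <- tibble::tibble(
        metric = "strut_peak_radius_mm", fov = fov, system = family,
        stent = stent_id, slice = mb$rays$slice,
        angle_deg = mb$rays$angle_deg, value = mb$rays$r_peak_mm)
    }

    if (length(spec$stents) == 2L) {
      gap_deg <- attr(spec, "gap_direction_deg")
      dd <- measure_distinction(
        vol,
        spec$stents[[1]]$center_offset_mm, spec$stents[[2]]$center_offset_mm,
        spec$stents[[1]]$diameter_mm, spec$stents[[2]]$diameter_mm,
        slices,
        gap_angle = if (!is.null(gap_deg)) gap_deg * pi / 180)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "distinction_pct", fov = fov, system = family,
        stent = paste(entry$phantom, "pair", sep = "_"),
        location = dd$per_location$slice,
        value = dd$per_location$distinction_pct)
    }
  }
  list(measurements = do.call(rbind, rows),
       detail = do.call(rbind, detail), volumes = noisy)
}

#' Simulate the reader study from measured image quality
#'
#' Converts each system's measured quantitative metrics into latent image
#' quality and draws 5-point Likert scores for two readers over two
#' sessions ([simulate_reader_scores()]). The latent scales are fixed
#' generator conventions (documented in the methods vignette): blooming
#' maps through `(28 - blooming%) / 7`, distinction through
#' `(distinction% - 65) / 15`, and overall stent appearance through the
#' mean of the blooming scale and `(0.45 - diameter error) / 0.18`.
#'
#' @param measurements Measurement tibble from [measure_experiment()].
#' @param cfg An `experiment_config`.
#' @param master_seed Override of `cfg$master_seed`.
#' @return Tidy score tibble: metric, fov, system, item, reader, session,
#'   score.
#' @export
simulate_study_scores <- function(measurements, cfg,
                                  master_seed = cfg$master_seed) {
  rd <- cfg$reader
  metrics <- c(stent_appearance = 1L, blooming = 2L,
               inter_stent_visibility = 3L)
  agg <- stats::aggregate(value ~ metric + fov + system + stent,
                          data = measurements, FUN = mean)
  out <- list()
  for (m in names(metrics)) {
    if (m == "inter_stent_visibility" &&
        !any(agg$metric == "distinction_pct")) next
    seed_m <- master_seed * 1000 + 900 + metrics[[m]]
    for (fov in unique(agg$fov)) {
      lat <- list()
      for (sys in unique(agg$system)) {
        sel <- agg[agg$fov == fov & agg$system == sys, ]
        bl <- sel$value[sel$metric == "blooming_pct"]
        er <- sel$value[sel$metric == "diameter_abs_error_mm"]
        di <- sel$value[sel$metric == "distinction_pct"]
        base <- switch(m,
          blooming = (28 - bl) / 7,
          stent_appearance = ((28 - bl) / 7 + (0.45 - er) / 0.18) / 2,
          inter_stent_visibility = (di - 65) / 15)
        # recycle per-stent quality over the requested presentations
        lat[[sys]] <- rep_len(base, rd$n_items)
      }
      item_eff <- withr::with_seed(seed_m + as.integer(fov),
                                   stats::rnorm(rd$n_items, 0, rd$item_sd))
      for (sys in names(lat)) {
        rs <- simulate_reader_scores(
          lat[[sys]] + item_eff, rd$reader_bias, rd$cut_points, rd$noise_sd,
          seed = seed_m + as.integer(fov) +
            7L * match(sys, sort(names(lat))),
          n_sessions = rd$n_sessions, metric_label = m)
        d <- dim(rs$scores)
        out[[length(out) + 1L]] <- tibble::tibble(
          metric = m, fov = fov, system = sys,
          item = rep(seq_len(d[1]), times = d[2] * d[3]),
          reader = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
          session = rep(seq_len(d[3]), each = d[1] * d[2]),
          score = c(rs$scores))
      }
    }
  }
  do.call(rbind, out)
}

#' Reader reliability report
#'
#' Inter-reader ICC (two readers, first session) and intra-reader ICC
#' (session 1 vs session 2 within each reader, averaged over readers), both
#' two-way consistency for the mean of two ratings ([icc_consistency()]).
#' Pooling across evaluations is either `"concatenated"` (one matrix over
#' all metric x FOV x item rows, the default) or `"per_metric"` (ICC per
#' metric, then averaged).
#'
#' @param scores Score tibble from [simulate_study_scores()].
#' @param pool `"concatenated"` or `"per_metric"`.
#' @return A list: `inter`, `intra` (ICC values), `pool`, and
#'   `inter_classification`.
#' @export
icc_report <- function(scores, pool = c("concatenated", "per_metric")) {
  pool <- match.arg(pool)
  one <- function(d) {
    d$key <- paste(d$metric, d$fov, d$system, d$item)
    s1 <- d[d$session == 1, ]
    m_inter <- stats::reshape(
      data.frame(key = s1$key, reader = s1$reader, score = s1$score),
      idvar = "key", timevar = "reader", direction = "wide")
    inter <- icc_consistency(as.matrix(m_inter[, -1]))$icc
    intras <- vapply(unique(d$reader), function(r) {
      dr <- d[d$reader == r, ]
      m <- stats::reshape(
        data.frame(key = dr$key, session = dr$session, score = dr$score),
        idvar = "key", timevar = "session", direction = "wide")
      icc_consistency(as.matrix(m[, -1]))$icc
    }, numeric(1))
    c(inter = inter, intra = mean(intras))
  }
  res <- if (pool == "concatenated") {
    one(scores)
  } else {
    rowMeans(vapply(split(scores, scores$metric), one, numeric(2)))
  }
  cls <- if (is.nan(res[["inter"]])) NA_character_ else
    if (res[["inter"]] < 0.5) "poor" else if (res[["inter"]] < 0.75)
      "moderate" else if (res[["inter"]] <= 0.9) "good" else "excellent"
  list(inter = unname(res[["inter"]]), intra = unname(res[["intra"]]),
       pool = pool, inter_classification = cls)
}

#' Run the full in-silico experiment
#'
#' End-to-end driver: simulate all phantom x system volumes, run the three
#' quantitative metrics with per-location replication, simulate the reader
#' study, and build the summary comparison report. With `out_dir` set, the
#' degraded volumes (NIfTI), per-location and per-line CSVs, score CSV,
#' summary CSV/JSON and a run log (seeds, configuration hash, package
#' version) are written; identical configurations yield byte-identical
#' summary files.
#'
#' @param cfg An `experiment_config`.
#' @param out_dir Output directory (default `cfg$out_dir`; `NULL` writes
#'   nothing).
#' @param write_volumes Write NIfTI volumes when `out_dir` is set.
#' @return A list: `measurements`, `detail`, `scores`, `report`, `icc`,
#'   `volumes`, `config`, `provenance`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = cfg$out_dir,
                           write_volumes = TRUE) {
  set <- simulate_volumes(cfg)
  meas <- measure_experiment(set, cfg)
  scores <- simulate_study_scores(meas$measurements, cfg)
  report <- summarize_comparison(
    meas$measurements[meas$measurements$metric != "diameter_mm", ], scores)
  icc <- icc_report(scores)
  prov <- list(config_hash = rlang::hash(cfg),
               master_seed = cfg$master_seed,
               package_version = as.character(utils::packageVersion("stentsim")))
  res <- list(measurements = meas$measurements, detail = meas$detail,
              scores = scores, report = report, icc = icc,
              volumes = meas$volumes, config = cfg, provenance = prov)
  if (!is.null(out_dir)) .write_experiment(res, out_dir, write_volumes)
  res
}

.write_csv_prov <- function(df, path, prov) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# stentsim %s", prov$package_version),
               sprintf("# config_hash: %s", prov$config_hash),
               sprintf("# master_seed: %d", prov$master_seed)), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
}

.write_experiment <- function(res, out_dir, write_volumes) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- res$provenance
  .write_csv_prov(res$measurements, file.path(out_dir, "measurements.csv"), prov)
  .write_csv_prov(res$detail, file.path(out_dir, "measurement_detail.csv"), prov)
  .write_csv_prov(res$scores, file.path(out_dir, "reader_scores.csv"), prov)
  .write_csv_prov(res$report, file.path(out_dir, "summary.csv"), prov)
  jsonlite::write_json(
    list(provenance = prov, report = res$report, icc = res$icc),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (write_volumes) {
    for (nm in names(res$volumes)) {
      f <- file.path(out_dir, paste0(gsub("\\|", "_", nm), ".nii.gz"))
      write_volume_nifti(res$volumes[[nm]], f)
    }
  }
  log <- c(provenance = list(prov),
           list(seeds = list(scheme = "master_seed * 1000 + volume_index",
                             master_seed = prov$master_seed),
                files = list.files(out_dir)))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
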
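# Fixture builders shared by the measurement and acceptance tests. All
# fixtures are generated in code at test time.

# Single-stent phantom with ground-truth ring diameter d.
single_stent_phantom <- function(d, label = sprintf("d%.1f", d)) {
  phantom_spec(stent_spec(d), vessel_lumen_diameter_mm = d + 2, label = label)
}

# Image a single-ring phantom through `cfg` (noiseless unless a seed is
# given); n_slices = 1 keeps parameter-recovery fixtures cheap.
ring_volume <- function(d, cfg, seed = NULL, n_slices = 1L, extent_mm = NULL) {
  spec <- single_stent_phantom(d)
  truth <- rasterize_phantom(spec, fine_spacing(cfg), extent_mm = extent_mm,
                             n_slices = n_slices,
                             slice_spacing_mm = cfg$slice_thickness_mm)
  apply_system(truth, cfg, seed = seed, add_noise = !is.null(seed))
}

# Noiseless default-design imaging set, built once per test run and shared
# (the expensive rendering dominates; re-noising per seed is cheap).
.shared <- new.env(parent = emptyenv())

acceptance_imaging_set <- function() {
  if (is.null(.shared$set)) {
    .shared$cfg <- experiment_config()
    .shared$set <- simulate_volumes(.shared$cfg)
  }
  list(cfg = .shared$cfg, set = .shared$set)
}
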
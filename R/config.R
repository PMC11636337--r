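cfg_get <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[k]])) {
      if (required) stop(sprintf("config field '%s' is required", path))
      return(default)
    }
    node <- node[[k]]
  }
  node
}

build_source <- function(src, i) {
  type <- src$type
  if (is.null(type))
    stop(sprintf("config field 'sources[%d].type' is required", i))
  if (type == "dipole") {
    dipole_source(
      position_mm = cfg_get(src, "position_mm", required = TRUE),
      strength_hz_mm3 = cfg_get(src, "strength_hz_mm3", required = TRUE),
      exclusion_radius_mm = cfg_get(src, "exclusion_radius_mm", 15))
  } else if (type == "lead") {
    path <- if (!is.null(src$helix)) {
      h <- src$helix
      helical_lead_path(cfg_get(h, "radius_mm", required = TRUE),
                        cfg_get(h, "pitch_mm", required = TRUE),
                        cfg_get(h, "n_turns", required = TRUE),
                        cfg_get(h, "center_mm", c(0, 0, 0)),
                        cfg_get(h, "points_per_turn", 96))
    } else if (!is.null(src$path)) {
      do.call(rbind, lapply(src$path, as.numeric))
    } else {
      stop(sprintf("config field 'sources[%d]' needs 'helix' or 'path'", i))
    }
    lead_source(path,
                cfg_get(src, "per_point_strength_hz_mm3", required = TRUE),
                cfg_get(src, "tip_strength_hz_mm3", 0),
                cfg_get(src, "exclusion_radius_mm", 3))
  } else {
    stop(sprintf("config field 'sources[%d].type' must be 'dipole' or 'lead'",
                 i))
  }
}

#' Parse a scene/pipeline configuration
#'
#' Accepts a YAML file path or an equivalent nested list and returns the
#' validated objects the pipeline runs on. Schema violations are reported
#' with their field paths. See the packaged examples under
#' `system.file("extdata", "configs", package = "b0gate")`.
#'
#' @param config YAML file path or nested list.
#' @return List with `label`, `scene`, `acq`, `motions`,
#'   `static_positions_mm`, `analysis`, and the raw `config`.
#' @export
read_scene_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")

  grid <- grid3d(cfg_get(config, "grid.shape", c(128L, 128L, 64L)),
                 cfg_get(config, "grid.voxel_size_mm", 2),
                 cfg_get(config, "grid.origin_mm", NULL))
  target <- target_sphere(cfg_get(config, "target.center_mm", c(0, 0, 0)),
                          cfg_get(config, "target.radius_mm", 15))
  sources <- lapply(seq_along(config$sources),
                    function(i) build_source(config$sources[[i]], i))
  scene <- phantom_scene(
    grid, target, sources,
    water_magnitude = cfg_get(config, "scene.water_magnitude", 1),
    background_magnitude = cfg_get(config, "scene.background_magnitude", 0.25),
    background_field_hz = cfg_get(config, "scene.background_field_hz", 0))

  acq <- acquisition_config(
    delta_te_s = cfg_get(config, "acquisition.delta_te_s", 0.002),
    noise_sd = cfg_get(config, "acquisition.noise_sd", 0.02),
    void_magnitude_threshold =
      cfg_get(config, "acquisition.void_magnitude_threshold", 0.1),
    n_motion_phases = cfg_get(config, "acquisition.n_motion_phases", 16),
    seed = cfg_get(config, "acquisition.seed", 1))

  motion_cfg <- config$motion
  if (is.null(motion_cfg))
    motion_cfg <- list(list(amplitude_pp_mm = 20, period_s = 4,
                            baseline_mm = 10))
  motions <- lapply(motion_cfg, function(m) {
    motion_pattern(cfg_get(m, "amplitude_pp_mm", required = TRUE),
                   cfg_get(m, "period_s", required = TRUE),
                   cfg_get(m, "exponent", 4),
                   cfg_get(m, "axis", c(0, 0, 1)),
                   cfg_get(m, "phase_offset_rad", 0),
                   cfg_get(m, "baseline_mm", 0))
  })

  positions <- cfg_get(config, "static_positions_mm", c(-10, -5, 0, 5, 10))

  analysis <- list(
    n_bands = cfg_get(config, "analysis.shells.n_bands", 15),
    band_width_mm = cfg_get(config, "analysis.shells.band_width_mm", 1),
    central_fractions = cfg_get(config, "analysis.central_fractions",
                                c(0.5, 0.95)),
    bw = bandwidth_config(
      cfg_get(config, "analysis.readout_bandwidth_hz_per_mm", 450)))

  list(label = cfg_get(config, "label", "scene"),
       scene = scene, acq = acq, motions = motions,
       static_positions_mm = as.numeric(positions),
       analysis = analysis, config = config)
}

#' Example configuration for an implant (CIED) setup
#'
#' One point-dipole implant at `distance_mm` from isocenter along an oblique
#' (x+z) direction, a water target sphere at isocenter, cos^4 respiratory
#' motion with 20 mm peak-to-peak amplitude at 15 breaths per minute, and
#' five static target positions from -10 to +10 mm. `distance_mm = NA` gives
#' the implant-free reference setup. The default dipole strength is set so
#' the 175 mm geometry produces target-region offsets of order 100 Hz.
#'
#' @param distance_mm Implant distance from isocenter (mm), or `NA` for the
#'   implant-free reference.
#' @param strength_hz_mm3 Dipole amplitude coefficient.
#' @param grid_shape,voxel_size_mm Desk-scale evaluation grid.
#' @param noise_sd,seed Acquisition noise level and RNG seed.
#' @param label Optional configuration label.
#' @return A configuration list for [run_pipeline()] / [read_scene_config()].
#' @export
config_implant <- function(distance_mm = 175, strength_hz_mm3 = 1.1e9,
                           grid_shape = c(64, 64, 48), voxel_size_mm = 3,
                           noise_sd = 0.02, seed = 1,
                           label = NULL) {
  sources <- list()
  if (!is.na(distance_mm)) {
    u <- c(1, 0, 1) / sqrt(2)
    sources <- list(list(type = "dipole",
                         position_mm = as.numeric(distance_mm * u),
                         strength_hz_mm3 = strength_hz_mm3,
                         exclusion_radius_mm = 15))
  }
  if (is.null(label))
    label <- if (is.na(distance_mm)) "no_implant"
             else sprintf("implant_%gmm", distance_mm)
  list(label = label,
       grid = list(shape = as.integer(grid_shape),
                   voxel_size_mm = voxel_size_mm),
       target = list(center_mm = c(0, 0, 0), radius_mm = 15),
       scene = list(water_magnitude = 1, background_magnitude = 0.25),
       sources = sources,
       acquisition = list(delta_te_s = 0.002, noise_sd = noise_sd,
                          void_magnitude_threshold = 0.1,
                          n_motion_phases = 16, seed = seed),
       motion = list(list(amplitude_pp_mm = 20, period_s = 4, exponent = 4,
                          axis = c(0, 0, 1), baseline_mm = 10)),
       static_positions_mm = c(-10, -5, 0, 5, 10))
}

#' Example configuration for a helically wrapped lead setup
#'
#' A lead wrapped around a cylindrical insert (helix around z) with an extra
#' tip dipole, cardiorespiratory motion (cos^4 respiratory plus a 2 mm
#' peak-to-peak, 1 s cardiac cos^4 component), and seven static positions.
#'
#' @param per_point_strength_hz_mm3,tip_strength_hz_mm3 Lead dipole
#'   coefficients.
#' @param grid_shape,voxel_size_mm Desk-scale evaluation grid.
#' @param noise_sd,seed Acquisition noise level and RNG seed.
#' @param label Optional configuration label.
#' @return A configuration list for [run_pipeline()] / [read_scene_config()].
#' @export
config_lead <- function(per_point_strength_hz_mm3 = 1500,
                        tip_strength_hz_mm3 = 2e5,
                        grid_shape = c(72, 72, 64), voxel_size_mm = 1,
                        noise_sd = 0.02, seed = 1, label = "lead") {
  list(label = label,
       grid = list(shape = as.integer(grid_shape),
                   voxel_size_mm = voxel_size_mm),
       target = list(center_mm = c(0, 0, 0), radius_mm = 8),
       scene = list(water_magnitude = 1, background_magnitude = 0.25),
       sources = list(list(
         type = "lead",
         helix = list(radius_mm = 16, pitch_mm = 6, n_turns = 3,
                      center_mm = c(0, 0, 0), points_per_turn = 128),
         per_point_strength_hz_mm3 = per_point_strength_hz_mm3,
         tip_strength_hz_mm3 = tip_strength_hz_mm3,
         exclusion_radius_mm = 3)),
       acquisition = list(delta_te_s = 0.002, noise_sd = noise_sd,
                          void_magnitude_threshold = 0.1,
                          n_motion_phases = 16, seed = seed),
       motion = list(
         list(amplitude_pp_mm = 20, period_s = 4, exponent = 4,
              axis = c(0, 0, 1), baseline_mm = 10),
         list(amplitude_pp_mm = 2, period_s = 1, exponent = 4,
              axis = c(1, 0, 0), baseline_mm = 0)),
       static_positions_mm = seq(-10, 10, length.out = 7))
}
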
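#' Run the full B0-mapping eligibility pipeline
#'
#' Executes, from one configuration: simulation of the wrapped static series
#' and the dynamic (free-breathing) acquisition; region-growing unwrapping of
#' every map (with branch re-referencing via [rereference_branch()] so
#' independently unwrapped maps are comparable); target-contour and, for lead
#' setups, distance-shell region construction; per-position and group-wise
#' Bland-Altman statistics; Hz-to-mm conversion; and the wrap-presence
#' eligibility verdict. Fully reproducible from the configuration and seed.
#'
#' The target area used for the wrap count is the union of the target-sphere
#' contours over the static positions (the excursion envelope of the moving
#' target, analogous to an internal target volume).
#'
#' @param config YAML path or configuration list (see [read_scene_config()],
#'   [config_implant()], [config_lead()]).
#' @param out_dir Optional output directory: writes `report.json`,
#'   `positions.csv`, `shells.csv` (lead setups), and NIfTI intermediates of
#'   the dynamic map.
#' @param seed Optional override of `acquisition.seed`.
#' @param write_nifti Write NIfTI intermediates when `out_dir` is given.
#' @param verbose Log progress to stderr.
#' @return List of class `b0gate_pipeline` with elements `report`
#'   ([eligibility_report][decide_eligibility()]), `position_table`,
#'   `pooled` ([agreement_result][bland_altman()]), `shell_table` (or
#'   `NULL`), `dynamic_map`, `static_maps`, `parsed` (parsed config).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         write_nifti = TRUE, verbose = FALSE) {
  parsed <- read_scene_config(config)
  if (!is.null(seed)) parsed$acq$seed <- as.integer(seed)
  scene <- parsed$scene
  acq <- parsed$acq
  an <- parsed$analysis
  say <- function(...) if (verbose) message(sprintf(...))

  axis <- parsed$motions[[1]]$axis
  positions <- parsed$static_positions_mm

  say("simulating %d static positions", length(positions))
  static_maps <- lapply(seq_along(positions), function(i) {
    acq_i <- acq
    acq_i$seed <- acq$seed + i
    a <- acquire_static(scene, positions[i] * axis, acq_i)
    rereference_branch(
      region_growing_unwrap(a, acq$void_magnitude_threshold))
  })

  say("simulating dynamic acquisition (%d motion phases)",
      acq$n_motion_phases)
  dyn_acq <- acquire_dynamic(scene, parsed$motions, acq)
  dynamic_map <- rereference_branch(
    region_growing_unwrap(dyn_acq, acq$void_magnitude_threshold))

  say("agreement statistics")
  per_position <- lapply(seq_along(positions), function(i) {
    roi <- sphere_mask(scene$target, positions[i] * axis, scene$grid)
    bland_altman(paired_voxels(static_maps[[i]], dynamic_map, roi,
                               sprintf("position %+g mm", positions[i])),
                 an$central_fractions)
  })
  pooled <- bland_altman(
    pool_pairs(lapply(seq_along(positions), function(i) {
      roi <- sphere_mask(scene$target, positions[i] * axis, scene$grid)
      paired_voxels(static_maps[[i]], dynamic_map, roi)
    }), label = paste0(parsed$label, " pooled")),
    an$central_fractions)
  position_table <- do.call(rbind, lapply(per_position, as.data.frame))

  has_lead <- any(vapply(scene$sources, inherits, logical(1), "lead_source"))
  shell_table <- NULL
  if (has_lead) {
    say("distance-shell analysis")
    avg_static <- average_static(static_maps)
    void <- !avg_static$valid_mask
    shells <- distance_shells(void, an$n_bands, an$band_width_mm, scene$grid)
    shell_table <- as.data.frame(
      shell_profile(avg_static, dynamic_map, shells, an$central_fractions))
  }

  target_area <- Reduce(`|`, lapply(positions, function(p) {
    sphere_mask(scene$target, p * axis, scene$grid)
  }))
  provenance <- list(seed = acq$seed, config_hash = config_hash(parsed$config))
  report <- decide_eligibility(dynamic_map, target_area, pooled,
                               an$bw, parsed$label, provenance)
  report$mean_offset_hz_range <-
    range(vapply(per_position, `[[`, numeric(1), "mean_of_means_hz"))

  out <- structure(list(report = report, position_table = position_table,
                        pooled = pooled, shell_table = shell_table,
                        dynamic_map = dynamic_map, static_maps = static_maps,
                        parsed = parsed),
                   class = "b0gate_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    write.csv(position_table, file.path(out_dir, "positions.csv"),
              row.names = FALSE)
    if (!is.null(shell_table))
      write.csv(shell_table, file.path(out_dir, "shells.csv"),
                row.names = FALSE)
    if (write_nifti) {
      write_nifti_volume(dynamic_map$values_hz, scene$grid,
                         file.path(out_dir, "dynamic_offresonance_hz.nii.gz"))
      write_nifti_volume(dynamic_map$wrap_count, scene$grid,
                         file.path(out_dir, "dynamic_wrap_count.nii.gz"))
      write_nifti_volume(dynamic_map$magnitude, scene$grid,
                         file.path(out_dir, "dynamic_magnitude.nii.gz"))
    }
    say("wrote outputs to %s", out_dir)
  }
  out
}

#' @export
print.b0gate_pipeline <- function(x, ...) {
  print(x$report)
  cat(sprintf("  %d static positions; pooled over %d voxel pairs\n",
              nrow(x$position_table), x$pooled$n_pairs))
  if (!is.null(x$shell_table))
    cat(sprintf("  shell profile: %d bands\n", nrow(x$shell_table)))
  invisible(x)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Simulate and write the wrapped acquisitions of a configuration
#'
#' The simulation half of [run_pipeline()]: writes the wrapped static series
#' and the dynamic acquisition as NIfTI phase/magnitude pairs
#' (`static_<k>_*`, `dynamic_*`).
#'
#' @param config YAML path or configuration list.
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @return Character vector of file paths, invisibly.
#' @export
simulate_scene <- function(config, out_dir, seed = NULL) {
  parsed <- read_scene_config(config)
  if (!is.null(seed)) parsed$acq$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  axis <- parsed$motions[[1]]$axis
  paths <- character(0)
  for (i in seq_along(parsed$static_positions_mm)) {
    acq_i <- parsed$acq
    acq_i$seed <- parsed$acq$seed + i
    a <- acquire_static(parsed$scene,
                        parsed$static_positions_mm[i] * axis, acq_i)
    paths <- c(paths, write_acquisition_nifti(
      a, file.path(out_dir, sprintf("static_%02d", i))))
  }
  d <- acquire_dynamic(parsed$scene, parsed$motions, parsed$acq)
  paths <- c(paths, write_acquisition_nifti(d, file.path(out_dir, "dynamic")))
  invisible(paths)
}
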
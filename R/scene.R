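#' Spherical water target
#'
#' @param center_mm Sphere center at rest (mm, isocenter frame).
#' @param radius_mm Sphere radius (mm), > 0.
#' @return An object of class `target_sphere`.
#' @export
target_sphere <- function(center_mm = c(0, 0, 0), radius_mm = 15) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stop("target.center_mm must be a finite 3-vector")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("target.radius_mm must be > 0")
  structure(list(center_mm = center_mm, radius_mm = as.numeric(radius_mm)),
            class = "target_sphere")
}

#' Dual-echo acquisition parameters
#'
#' `delta_te_s` sets the Hz-per-wrap scale of the phase-difference map: an
#' off-resonance of 1/delta_te_s produces one full 2*pi wrap, so the default
#' 2 ms gives an unambiguous range of +/- 250 Hz. Complex Gaussian noise of
#' standard deviation `noise_sd` (per real/imaginary channel, relative to a
#' unit-magnitude signal) is added to the reconstructed complex image.
#'
#' @param delta_te_s Echo-time spacing in seconds, > 0. Default 2 ms.
#' @param noise_sd Complex-noise SD as a fraction of unit magnitude.
#' @param void_magnitude_threshold Fraction of the maximum magnitude below
#'   which a voxel is treated as signal void. In [0, 1).
#' @param n_motion_phases Temporal samples per common motion period for
#'   dynamic acquisition, >= 4.
#' @param seed Integer RNG seed; all acquisition noise flows from it.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(delta_te_s = 0.002, noise_sd = 0.02,
                               void_magnitude_threshold = 0.1,
                               n_motion_phases = 16, seed = 1L) {
  if (!is.finite(delta_te_s) || delta_te_s <= 0)
    stop("acquisition.delta_te_s must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("acquisition.noise_sd must be >= 0")
  if (!is.finite(void_magnitude_threshold) ||
      void_magnitude_threshold < 0 || void_magnitude_threshold >= 1)
    stop("acquisition.void_magnitude_threshold must be in [0, 1)")
  if (!is.finite(n_motion_phases) || n_motion_phases < 4)
    stop("acquisition.n_motion_phases must be >= 4")
  structure(list(delta_te_s = as.numeric(delta_te_s),
                 noise_sd = as.numeric(noise_sd),
                 void_magnitude_threshold = as.numeric(void_magnitude_threshold),
                 n_motion_phases = as.integer(n_motion_phases),
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Phantom scene: grid, water target, and field-perturbing sources
#'
#' The scene emulates a motion phantom at isocenter: a water-filled sphere
#' (relative magnitude `water_magnitude`) inside a signal-bearing background
#' (`background_magnitude`), optionally perturbed by an implant dipole and/or
#' lead sources. A spatially uniform `background_field_hz` can be added to
#' mimic an overall centre-frequency offset. Displacements translate the
#' scene rigidly: target and sources move together, as a thoracic target and
#' an implanted device do under respiration.
#'
#' @param grid A [grid3d()].
#' @param target A [target_sphere()].
#' @param sources List of [dipole_source()] / [lead_source()] objects (may be
#'   empty: the implant-free reference setup). All source points must lie
#'   outside the target sphere at rest.
#' @param water_magnitude Relative signal of the water target.
#' @param background_magnitude Relative signal of the surrounding medium.
#' @param background_field_hz Uniform off-resonance offset (Hz).
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(grid, target, sources = list(),
                          water_magnitude = 1, background_magnitude = 0.25,
                          background_field_hz = 0) {
  stopifnot(inherits(grid, "grid3d"), inherits(target, "target_sphere"))
  if (inherits(sources, c("dipole_source", "lead_source")))
    sources <- list(sources)
  for (s in sources) {
    pts <- source_points(s)$pts
    d <- sqrt(colSums((t(pts) - target$center_mm)^2))
    if (any(d <= target$radius_mm))
      stop("sources must lie outside the target sphere at rest")
  }
  if (!is.finite(water_magnitude) || water_magnitude < 0 ||
      !is.finite(background_magnitude) || background_magnitude < 0)
    stop("magnitudes must be >= 0")
  structure(list(grid = grid, target = target, sources = sources,
                 water_magnitude = as.numeric(water_magnitude),
                 background_magnitude = as.numeric(background_magnitude),
                 background_field_hz = as.numeric(background_field_hz)),
            class = "phantom_scene")
}

#' Instantaneous off-resonance field and magnitude of a displaced scene
#'
#' Evaluates the scene rigidly translated by `displacement_mm`: source fields
#' are evaluated at their translated positions and the water sphere is
#' translated likewise. Magnitude is `water_magnitude` inside the displaced
#' sphere, `background_magnitude` elsewhere, and 0 inside any source
#' exclusion radius (signal void).
#'
#' @param scene A [phantom_scene()].
#' @param displacement_mm Length-3 rigid displacement (mm).
#' @return A list with `values_hz` and `magnitude` arrays, a logical
#'   `valid_mask`, and the `grid`.
#' @export
scene_offresonance <- function(scene, displacement_mm = c(0, 0, 0)) {
  stopifnot(inherits(scene, "phantom_scene"))
  displacement_mm <- as.numeric(displacement_mm)
  stopifnot(length(displacement_mm) == 3L, all(is.finite(displacement_mm)))
  grid <- scene$grid

  values <- array(scene$background_field_hz, grid$shape)
  valid <- array(TRUE, grid$shape)
  if (length(scene$sources) > 0) {
    sp <- lapply(scene$sources, source_points)
    pts <- do.call(rbind, lapply(sp, `[[`, "pts"))
    pts <- sweep(pts, 2, displacement_mm, `+`)
    strength <- unlist(lapply(sp, `[[`, "strength"))
    excl <- unlist(lapply(sp, function(x) rep_len(x$excl, nrow(x$pts))))
    f <- sum_point_fields(pts, strength, excl, grid)
    values <- values + f$values_hz
    valid <- f$valid_mask
  }

  magnitude <- array(scene$background_magnitude, grid$shape)
  magnitude[sphere_mask(scene$target, displacement_mm, grid)] <-
    scene$water_magnitude
  magnitude[!valid] <- 0

  list(values_hz = values, magnitude = magnitude, valid_mask = valid,
       grid = grid)
}

#' Wrapped dual-echo phase-difference acquisition
#'
#' Container for a simulated acquisition: wrapped phase in (-pi, pi], a
#' magnitude volume, the echo-time spacing, and the grid. Normally produced
#' by [acquire_static()] / [acquire_dynamic()].
#'
#' @param phase_rad 3D array of wrapped phase, strictly within (-pi, pi].
#' @param magnitude 3D array of non-negative magnitudes.
#' @param delta_te_s Echo-time spacing in seconds.
#' @param grid A [grid3d()] matching both arrays.
#' @return An object of class `wrapped_acquisition`.
#' @export
wrapped_acquisition <- function(phase_rad, magnitude, delta_te_s, grid) {
  stopifnot(inherits(grid, "grid3d"))
  dims <- as.integer(grid$shape)
  if (!identical(dim(phase_rad), dims) || !identical(dim(magnitude), dims))
    stop("phase/magnitude shapes must match the grid")
  if (any(phase_rad <= -pi | phase_rad > pi, na.rm = TRUE))
    stop("phase must lie strictly within (-pi, pi]")
  if (any(magnitude < 0, na.rm = TRUE)) stop("magnitude must be >= 0")
  if (!is.finite(delta_te_s) || delta_te_s <= 0) stop("delta_te_s must be > 0")
  structure(list(phase_rad = phase_rad, magnitude = magnitude,
                 delta_te_s = as.numeric(delta_te_s), grid = grid),
            class = "wrapped_acquisition")
}

# Intravoxel dephasing: a linear field variation across a voxel attenuates
# the voxel's signal by |sinc(delta_phi/2)| per axis, where delta_phi is the
# phase span 2*pi*dTE*|df/dx|*h accumulated over the echo spacing. This is
# what empties out the steep-gradient shell around metal (the susceptibility
# signal void) and is also why magnitude works as an unwrapping quality map:
# low magnitude marks exactly the voxels whose phase is unreliable.
dephasing_attenuation <- function(values_hz, grid, delta_te_s) {
  att <- array(1, dim(values_hz))
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  for (ax in 1:3) {
    n <- grid$shape[ax]
    if (n < 2) next
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    take <- function(i) switch(ax, values_hz[i, , , drop = FALSE],
                               values_hz[, i, , drop = FALSE],
                               values_hz[, , i, drop = FALSE])
    grad <- (take(idx_p) - take(idx_m)) / (idx_p - idx_m)  # Hz per voxel
    att <- att * abs(sinc(pi * delta_te_s * abs(grad)))
  }
  att
}

# one motion-state complex snapshot of the scene
scene_snapshot_signal <- function(scene, displacement_mm, acq) {
  f <- scene_offresonance(scene, displacement_mm)
  phi <- wrap_to_pi(2 * pi * f$values_hz * acq$delta_te_s)
  mag <- f$magnitude *
    dephasing_attenuation(f$values_hz, scene$grid, acq$delta_te_s)
  as.vector(mag) * exp(1i * as.vector(phi))
}

# complex image -> wrapped_acquisition (noise applied to the complex signal)
signal_to_acquisition <- function(sig, acq, grid) {
  if (acq$noise_sd > 0) {
    set.seed(acq$seed)
    n <- length(sig)
    sig <- sig + complex(real = rnorm(n, 0, acq$noise_sd),
                         imaginary = rnorm(n, 0, acq$noise_sd))
  }
  phase <- Arg(sig)
  phase[phase <= -pi] <- pi
  wrapped_acquisition(array(phase, grid$shape), array(Mod(sig), grid$shape),
                      acq$delta_te_s, grid)
}

#' Simulate a static wrapped B0-map acquisition
#'
#' The scene is held at a fixed displacement; the wrapped phase is
#' `wrap_to_pi(2 * pi * df * delta_te_s)` and complex Gaussian noise is added
#' to the complex signal before taking phase and magnitude. Intravoxel
#' dephasing attenuates the magnitude where the field varies steeply across a
#' voxel, producing the characteristic signal-void shell around metal.
#' Deterministic for a given `acq$seed`.
#'
#' @param scene A [phantom_scene()].
#' @param displacement_mm Rigid scene displacement (mm).
#' @param acq An [acquisition_config()].
#' @return A [wrapped_acquisition()].
#' @export
acquire_static <- function(scene, displacement_mm = c(0, 0, 0), acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  signal_to_acquisition(scene_snapshot_signal(scene, displacement_mm, acq),
                        acq, scene$grid)
}

#' Simulate a dynamic (free-breathing) wrapped B0-map acquisition
#'
#' The complex signal is averaged over `acq$n_motion_phases` uniformly spaced
#' times across the least common period of the motion patterns (respiratory
#' and cardiac displacements add). The returned phase is the argument of the
#' time-averaged complex signal and the magnitude its modulus, so motion
#' attenuates magnitude and biases phase wherever the field at a voxel varies
#' over the cycle. Noise is added once, to the time-averaged signal, making a
#' zero-amplitude dynamic acquisition bit-identical to [acquire_static()] at
#' baseline for the same seed.
#'
#' @param scene A [phantom_scene()].
#' @param motion A [motion_pattern()] or a list of them (>= 1).
#' @param acq An [acquisition_config()].
#' @return A [wrapped_acquisition()].
#' @export
acquire_dynamic <- function(scene, motion, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (inherits(motion, "motion_pattern")) motion <- list(motion)
  if (length(motion) < 1) stop("at least one motion pattern is required")
  period <- common_period_s(motion)
  times <- (seq_len(acq$n_motion_phases) - 1) / acq$n_motion_phases * period

  sig <- complex(real = numeric(prod(scene$grid$shape)))
  for (t in times) {
    sig <- sig +
      scene_snapshot_signal(scene, motion_displacement(t, motion), acq)
  }
  signal_to_acquisition(sig / length(times), acq, scene$grid)
}
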
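#' Point-dipole susceptibility source
#'
#' A metallic implant is modelled as a magnetic point dipole aligned with the
#' main field. Its off-resonance footprint is
#' \deqn{\Delta f(r) = k \, (3\cos^2\theta - 1)/|r - r_0|^3,}
#' where \eqn{\theta} is the angle between \eqn{r - r_0} and the main-field
#' (z) axis and \eqn{k} is the amplitude coefficient in Hz mm^3. Inside
#' `exclusion_radius_mm` the dipole model does not hold and the signal is
#' treated as void.
#'
#' @param position_mm Length-3 source position (mm, isocenter frame).
#' @param strength_hz_mm3 Amplitude coefficient k (Hz mm^3).
#' @param exclusion_radius_mm Radius of the signal void / model-invalid zone.
#' @return An object of class `dipole_source`.
#' @examples
#' dipole_source(c(175, 0, 0), 5.4e8, 15)
#' @export
dipole_source <- function(position_mm, strength_hz_mm3,
                          exclusion_radius_mm = 15) {
  position_mm <- as.numeric(position_mm)
  if (length(position_mm) != 3L || any(!is.finite(position_mm)))
    stop("position_mm must be a finite 3-vector")
  if (!is.finite(strength_hz_mm3))
    stop("strength_hz_mm3 must be finite")
  if (!is.finite(exclusion_radius_mm) || exclusion_radius_mm <= 0)
    stop("exclusion_radius_mm must be > 0 (a zero-radius source is rejected)")
  structure(list(position_mm = position_mm,
                 strength_hz_mm3 = as.numeric(strength_hz_mm3),
                 exclusion_radius_mm = as.numeric(exclusion_radius_mm)),
            class = "dipole_source")
}

#' Pacing-lead source along a polyline
#'
#' A lead is modelled as a chain of weak point dipoles along its path plus an
#' extra dipole at the final path point representing the stronger perturbation
#' at the lead tip. The path must be sampled densely (consecutive points
#' closer than one voxel edge) so the superposition approximates a line
#' source; [lead_field()] enforces this against the evaluation grid.
#'
#' @param path Numeric matrix (n x 3), ordered path points in mm. At least 2.
#' @param per_point_strength_hz_mm3 Scalar or length-n dipole coefficients.
#' @param tip_strength_hz_mm3 Extra dipole coefficient at the last point.
#' @param exclusion_radius_mm Signal-void radius around every path point.
#' @return An object of class `lead_source`.
#' @seealso [helical_lead_path()]
#' @export
lead_source <- function(path, per_point_strength_hz_mm3,
                        tip_strength_hz_mm3 = 0, exclusion_radius_mm = 3) {
  path <- as.matrix(path)
  if (ncol(path) != 3L || nrow(path) < 2L || any(!is.finite(path)))
    stop("path must be a finite n x 3 matrix with n >= 2")
  k <- rep_len(as.numeric(per_point_strength_hz_mm3), nrow(path))
  if (any(!is.finite(k))) stop("per_point_strength_hz_mm3 must be finite")
  if (!is.finite(tip_strength_hz_mm3)) stop("tip_strength_hz_mm3 must be finite")
  if (!is.finite(exclusion_radius_mm) || exclusion_radius_mm <= 0)
    stop("exclusion_radius_mm must be > 0")
  structure(list(path = unname(path),
                 per_point_strength_hz_mm3 = k,
                 tip_strength_hz_mm3 = as.numeric(tip_strength_hz_mm3),
                 exclusion_radius_mm = as.numeric(exclusion_radius_mm)),
            class = "lead_source")
}

#' Helical lead path around a cylindrical insert
#'
#' @param radius_mm Helix (cylinder) radius.
#' @param pitch_mm Axial advance per turn.
#' @param n_turns Number of turns.
#' @param center_mm Center of the helix (mm); the helix axis is z.
#' @param points_per_turn Path sampling density.
#' @param phase_rad Azimuthal start angle.
#' @return An (n x 3) matrix of path points, centered axially on `center_mm`.
#' @export
helical_lead_path <- function(radius_mm, pitch_mm, n_turns,
                              center_mm = c(0, 0, 0), points_per_turn = 96,
                              phase_rad = 0) {
  stopifnot(radius_mm > 0, pitch_mm >= 0, n_turns > 0, points_per_turn >= 3)
  n <- max(2L, ceiling(n_turns * points_per_turn))
  u <- seq(0, n_turns, length.out = n)
  cbind(center_mm[1] + radius_mm * cos(2 * pi * u + phase_rad),
        center_mm[2] + radius_mm * sin(2 * pi * u + phase_rad),
        center_mm[3] + pitch_mm * (u - n_turns / 2))
}

source_points <- function(source) {
  if (inherits(source, "dipole_source")) {
    list(pts = matrix(source$position_mm, 1, 3),
         strength = source$strength_hz_mm3,
         excl = source$exclusion_radius_mm)
  } else if (inherits(source, "lead_source")) {
    pts <- source$path
    strength <- source$per_point_strength_hz_mm3
    if (source$tip_strength_hz_mm3 != 0) {
      pts <- rbind(pts, pts[nrow(pts), ])
      strength <- c(strength, source$tip_strength_hz_mm3)
    }
    list(pts = pts, strength = strength,
         excl = rep(source$exclusion_radius_mm, nrow(pts)))
  } else {
    stop("sources must be dipole_source or lead_source objects")
  }
}

sum_point_fields <- function(pts, strength, excl, grid) {
  res <- dipole_sum_field_cpp(pts, as.numeric(strength),
                              rep_len(as.numeric(excl), nrow(pts)),
                              grid_axis_mm(grid, 1), grid_axis_mm(grid, 2),
                              grid_axis_mm(grid, 3))
  offresonance_map(array(res$values_hz, grid$shape),
                   array(!res$invalid, grid$shape), grid)
}

#' Off-resonance field of a point dipole
#'
#' @param source A [dipole_source()].
#' @param grid A [grid3d()].
#' @return An [offresonance_map()] whose `valid_mask` is `FALSE` inside the
#'   exclusion radius.
#' @examples
#' g <- grid3d(c(17, 17, 17), 2)
#' f <- dipole_field(dipole_source(c(0, 0, 20), 1e5, 5), g)
#' @export
dipole_field <- function(source, grid) {
  stopifnot(inherits(source, "dipole_source"), inherits(grid, "grid3d"))
  sp <- source_points(source)
  sum_point_fields(sp$pts, sp$strength, sp$excl, grid)
}

#' Off-resonance field of a lead
#'
#' Superposition of [dipole_field()] over the path points plus the tip dipole.
#'
#' @param source A [lead_source()].
#' @param grid A [grid3d()].
#' @return An [offresonance_map()]; invalid within the exclusion radius of any
#'   path point.
#' @export
lead_field <- function(source, grid) {
  stopifnot(inherits(source, "lead_source"), inherits(grid, "grid3d"))
  step <- sqrt(rowSums(diff(source$path)^2))
  if (any(step > min(grid$voxel_size_mm)))
    stop("lead path is undersampled: consecutive points must be closer than one voxel")
  sp <- source_points(source)
  sum_point_fields(sp$pts, sp$strength, sp$excl, grid)
}
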
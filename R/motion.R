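#' Periodic cos^(2n) displacement pattern
#'
#' The standard breathing-motion law used for respiratory (and, with a shorter
#' period, cardiac) displacement:
#' \deqn{z(t) = z_0 - b \cos^{2n}(\pi t / \tau + \phi),}
#' with peak-to-peak amplitude \eqn{b}, period \eqn{\tau}, and even exponent
#' \eqn{2n} (default 4, the classic cos^4 pattern). The object spends most of
#' the cycle near the baseline \eqn{z_0} (exhale) with brief excursions to
#' \eqn{z_0 - b}.
#'
#' @param amplitude_pp_mm Peak-to-peak amplitude b (mm), >= 0.
#' @param period_s Period tau (s), > 0.
#' @param exponent Even exponent 2n >= 2; default 4.
#' @param axis Direction of motion (unit 3-vector; normalised on input).
#'   Default superior-inferior (z).
#' @param phase_offset_rad Phase offset phi.
#' @param baseline_mm Baseline position z0 (mm) along `axis`.
#' @return An object of class `motion_pattern`.
#' @examples
#' resp <- motion_pattern(20, 4)          # 20 mm p-p at 15 breaths/min
#' lujan_position(0, resp)                # extreme: z0 - b
#' lujan_position(2, resp)                # mid-cycle: z0
#' @export
motion_pattern <- function(amplitude_pp_mm, period_s, exponent = 4,
                           axis = c(0, 0, 1), phase_offset_rad = 0,
                           baseline_mm = 0) {
  if (!is.finite(amplitude_pp_mm) || amplitude_pp_mm < 0)
    stop("amplitude_pp_mm must be >= 0")
  if (!is.finite(period_s) || period_s <= 0)
    stop("period_s must be > 0")
  if (!is.finite(exponent) || exponent < 2 || exponent %% 2 != 0)
    stop("exponent must be even and >= 2")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 3L || !is.finite(nrm) || nrm == 0)
    stop("axis must be a nonzero 3-vector")
  structure(list(amplitude_pp_mm = as.numeric(amplitude_pp_mm),
                 period_s = as.numeric(period_s),
                 exponent = as.integer(exponent),
                 axis = axis / nrm,
                 phase_offset_rad = as.numeric(phase_offset_rad),
                 baseline_mm = as.numeric(baseline_mm)),
            class = "motion_pattern")
}

#' Displacement along a motion pattern's axis at time t
#'
#' @param t Time(s) in seconds (vectorised).
#' @param m A [motion_pattern()].
#' @return Displacement(s) in mm along `m$axis`.
#' @export
lujan_position <- function(t, m) {
  stopifnot(inherits(m, "motion_pattern"), all(is.finite(t)))
  m$baseline_mm -
    m$amplitude_pp_mm * cos(pi * t / m$period_s + m$phase_offset_rad)^m$exponent
}

#' Total 3D displacement from a set of motion patterns
#'
#' Displacements of the individual patterns (e.g. respiratory + cardiac) add.
#'
#' @param t A single time in seconds.
#' @param patterns A [motion_pattern()] or list of them.
#' @return Length-3 displacement vector in mm.
#' @export
motion_displacement <- function(t, patterns) {
  if (inherits(patterns, "motion_pattern")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1)
  Reduce(`+`, lapply(patterns, function(m) lujan_position(t, m) * m$axis))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# least common period of a list of motion patterns (periods resolved to 1 us)
common_period_s <- function(patterns) {
  us <- vapply(patterns, function(m) round(m$period_s * 1e6), numeric(1))
  Reduce(function(a, b) a * b / gcd_int(a, b), us) / 1e6
}
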
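#' Off-resonance (B0) map
#'
#' Container for an unwrapped off-resonance volume: values in Hz, a validity
#' mask (signal present and unwrapped), and the per-voxel number of 2*pi
#' additions applied during unwrapping. On the valid mask,
#' `values_hz = (phase_rad + 2*pi*wrap_count) / (2*pi*delta_te_s)`.
#'
#' @param values_hz 3D numeric array of off-resonance in Hz.
#' @param valid_mask 3D logical array.
#' @param grid A [grid3d()].
#' @param wrap_count Optional 3D integer array of applied 2*pi multiples
#'   (0 outside `valid_mask`). `NULL` for derived maps (e.g. averages).
#' @param delta_te_s Optional echo-time spacing the map was derived from.
#' @param magnitude Optional magnitude volume carried along unaltered.
#' @return An object of class `offresonance_map`.
#' @export
offresonance_map <- function(values_hz, valid_mask, grid, wrap_count = NULL,
                             delta_te_s = NULL, magnitude = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  dims <- as.integer(grid$shape)
  if (!identical(dim(values_hz), dims)) stop("values_hz shape must match grid")
  check_mask(valid_mask, grid, "valid_mask")
  if (any(!is.finite(values_hz[valid_mask])))
    stop("values must be finite on the valid mask")
  if (!is.null(wrap_count) && !identical(dim(wrap_count), dims))
    stop("wrap_count shape must match grid")
  structure(list(values_hz = values_hz, valid_mask = valid_mask,
                 wrap_count = wrap_count, delta_te_s = delta_te_s,
                 magnitude = magnitude, grid = grid),
            class = "offresonance_map")
}

#' @export
print.offresonance_map <- function(x, ...) {
  v <- x$values_hz[x$valid_mask]
  cat(sprintf("<offresonance_map> %s voxels, %d valid, range %.1f..%.1f Hz\n",
              paste(x$grid$shape, collapse = "x"), sum(x$valid_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Wrap phase into the half-open interval (-pi, pi]
#'
#' @param phase Numeric vector/array of phase in radians (finite).
#' @return `phase` reduced modulo 2*pi into (-pi, pi].
#' @examples
#' wrap_to_pi(c(0, 3 * pi, -pi))  # 0, pi, pi
#' @export
wrap_to_pi <- function(phase) {
  if (any(!is.finite(phase))) stop("phase must be finite")
  phase - 2 * pi * ceiling((phase - pi) / (2 * pi))
}

#' Quality-guided region-growing phase unwrapping
#'
#' Removes 2*pi phase wraps from a wrapped dual-echo acquisition using a
#' region-growing algorithm driven by both magnitude and phase: voxels below
#' `void_threshold * max(magnitude)` are excluded as signal void; growth
#' starts at the highest-magnitude voxel (or at `seed_voxel`) and proceeds
#' through a priority front ordered by magnitude, so unreliable low-signal
#' voxels are visited last and phase errors near voids cannot propagate into
#' high-signal regions. Each voxel's unwrapped phase is its wrapped phase
#' plus the 2*pi multiple closest to the mean of its already-unwrapped
#' 6-neighbours. Disconnected valid components are unwrapped independently,
#' each referenced to 0 wraps at its own seed; no information crosses a
#' signal void. The result is converted to Hz via the echo-time spacing.
#'
#' @param acq A [wrapped_acquisition()].
#' @param void_threshold Void threshold as a fraction of the maximum
#'   magnitude.
#' @param seed_voxel Optional linear (column-major, 1-based) voxel index to
#'   start growth from; must be above the void threshold.
#' @return An [offresonance_map()] with `wrap_count` filled in; magnitude and
#'   void mask are carried through unaltered.
#' @export
region_growing_unwrap <- function(acq, void_threshold = 0.1,
                                  seed_voxel = NULL) {
  stopifnot(inherits(acq, "wrapped_acquisition"))
  if (any(!is.finite(acq$phase_rad))) stop("wrapped phase contains NaN")
  if (!is.finite(void_threshold) || void_threshold < 0 || void_threshold >= 1)
    stop("void_threshold must be in [0, 1)")
  mx <- max(acq$magnitude)
  if (mx <= 0) stop("all voxels are void: magnitude is identically zero")
  thr <- void_threshold * mx
  seed0 <- if (is.null(seed_voxel)) -1L else as.integer(seed_voxel) - 1L
  res <- unwrap_rg_cpp(as.vector(acq$phase_rad), as.vector(acq$magnitude),
                       as.integer(acq$grid$shape), thr, seed0)
  valid <- array(res$valid, acq$grid$shape)
  values <- array(res$phase_unwrapped / (2 * pi * acq$delta_te_s),
                  acq$grid$shape)
  values[!valid] <- 0
  wraps <- array(res$wrap_count, acq$grid$shape)
  wraps[!valid] <- 0L
  offresonance_map(values, valid, acq$grid, wrap_count = wraps,
                   delta_te_s = acq$delta_te_s, magnitude = acq$magnitude)
}

#' Count phase wraps crossing a region
#'
#' Returns the number of distinct 2*pi branches among the valid voxels of the
#' region minus one: 0 means no wrap crosses the region, >= 1 means at least
#' one 2*pi discontinuity of the wrapped map lies inside it.
#'
#' @param map An [offresonance_map()] with `wrap_count` (i.e. produced by
#'   [region_growing_unwrap()]).
#' @param region_mask Logical array on the map's grid, with at least one
#'   `TRUE` voxel.
#' @return Integer wrap count, or `NA_integer_` (indeterminate) when the
#'   region is entirely void.
#' @export
wraps_in_region <- function(map, region_mask) {
  stopifnot(inherits(map, "offresonance_map"))
  if (is.null(map$wrap_count)) stop("map carries no wrap_count")
  check_mask(region_mask, map$grid, "region_mask")
  if (!any(region_mask)) stop("region_mask is empty")
  sel <- region_mask & map$valid_mask
  if (!any(sel)) return(NA_integer_)
  length(unique(as.vector(map$wrap_count[sel]))) - 1L
}

#' Re-reference the global 2*pi branch of an unwrapped map
#'
#' Region-growing unwrapping fixes the absolute branch arbitrarily (0 wraps
#' at the seed). Analogous to referencing a B0-map to the scanner centre
#' frequency, this shifts the whole map by an integer number of wraps so that
#' the modal (or median) wrap count over the valid voxels becomes zero,
#' making independently unwrapped maps comparable before differencing.
#'
#' @param map An [offresonance_map()] with `wrap_count`.
#' @param method `"mode"` (default) or `"median"` of the valid wrap counts.
#' @return The re-referenced [offresonance_map()].
#' @export
rereference_branch <- function(map, method = c("mode", "median")) {
  stopifnot(inherits(map, "offresonance_map"))
  if (is.null(map$wrap_count) || is.null(map$delta_te_s))
    stop("map carries no wrap_count/delta_te_s")
  method <- match.arg(method)
  k <- as.vector(map$wrap_count[map$valid_mask])
  shift <- if (method == "mode") {
    tab <- table(k)
    as.integer(names(tab)[which.max(tab)])
  } else {
    as.integer(round(median(k)))
  }
  if (shift == 0L) return(map)
  map$values_hz[map$valid_mask] <-
    map$values_hz[map$valid_mask] - shift / map$delta_te_s
  map$wrap_count[map$valid_mask] <- map$wrap_count[map$valid_mask] - shift
  map
}
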
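#' Voxel mask of a (displaced) target sphere
#'
#' A voxel belongs to the mask iff its center lies within the sphere radius
#' of the displaced center (center-in-region convention, no partial-volume
#' weighting).
#'
#' @param target A [target_sphere()].
#' @param displacement_mm Length-3 displacement of the sphere center (mm).
#' @param grid A [grid3d()].
#' @return Logical 3D array.
#' @export
sphere_mask <- function(target, displacement_mm = c(0, 0, 0), grid) {
  stopifnot(inherits(target, "target_sphere"), inherits(grid, "grid3d"))
  ctr <- target$center_mm + as.numeric(displacement_mm)
  dx2 <- (grid_axis_mm(grid, 1) - ctr[1])^2
  dy2 <- (grid_axis_mm(grid, 2) - ctr[2])^2
  dz2 <- (grid_axis_mm(grid, 3) - ctr[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(r2 <= target$radius_mm^2, grid$shape)
}

#' Detect signal voids from a magnitude volume
#'
#' A voxel is void iff its magnitude is strictly below
#' `threshold_fraction * max(magnitude)`.
#'
#' @param magnitude Non-negative 3D array.
#' @param threshold_fraction Fraction of the maximum magnitude.
#' @return Logical 3D array (TRUE = void).
#' @export
detect_void <- function(magnitude, threshold_fraction) {
  if (any(magnitude < 0)) stop("magnitude must be >= 0")
  mx <- max(magnitude)
  if (mx <= 0) stop("magnitude is identically zero: void undefined")
  magnitude < threshold_fraction * mx
}

#' Concentric distance shells around a signal void
#'
#' Computes the exact Euclidean distance (between voxel centers, in physical
#' mm) from every voxel to the nearest void voxel and partitions the
#' neighbourhood of the void into disjoint half-open bands
#' `[i*w, (i+1)*w)`, i = 0..n_bands-1. Void voxels belong to no shell. The
#' default reproduces 15 bands of 1 mm ("0-1 mm" ... "14-15 mm").
#'
#' @param void_mask Non-empty logical 3D array.
#' @param n_bands Number of distance bands.
#' @param band_width_mm Band width w in mm.
#' @param grid A [grid3d()].
#' @return An object of class `shell_set`: list with `shells` (list of
#'   logical arrays), `band_edges_mm` (n_bands x 2 matrix), `void_mask`, and
#'   the voxelwise `distance_mm` array.
#' @export
distance_shells <- function(void_mask, n_bands = 15, band_width_mm = 1,
                            grid) {
  stopifnot(inherits(grid, "grid3d"))
  check_mask(void_mask, grid, "void_mask")
  if (!any(void_mask)) stop("void_mask is empty")
  if (n_bands < 1 || band_width_mm <= 0)
    stop("n_bands must be >= 1 and band_width_mm > 0")
  dist <- array(edt_mm_cpp(as.vector(void_mask), as.integer(grid$shape),
                           grid$voxel_size_mm),
                grid$shape)
  edges <- cbind(lo = (seq_len(n_bands) - 1) * band_width_mm,
                 hi = seq_len(n_bands) * band_width_mm)
  shells <- lapply(seq_len(n_bands), function(i) {
    dist >= edges[i, 1] & dist < edges[i, 2] & !void_mask
  })
  structure(list(shells = shells, band_edges_mm = edges,
                 void_mask = void_mask, distance_mm = dist),
            class = "shell_set")
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("<shell_set> %d bands of %.3g mm, %d void voxels, sizes: %s\n",
              nrow(x$band_edges_mm),
              x$band_edges_mm[1, 2] - x$band_edges_mm[1, 1],
              sum(x$void_mask),
              paste(vapply(x$shells, sum, integer(1)), collapse = " ")))
  invisible(x)
}
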
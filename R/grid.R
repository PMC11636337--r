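#' Regular 3D voxel grid in the isocenter frame
#'
#' Defines the coordinate frame of all simulated volumes. Coordinates are in
#' mm, right-handed, with the main magnetic field along the third (z) axis and
#' the machine isocenter at (0, 0, 0). `origin_mm` gives the position of the
#' center of voxel (1, 1, 1); by default the grid is centered on isocenter.
#'
#' @param shape Integer vector of length 3: voxel counts (nx, ny, nz).
#' @param voxel_size_mm Voxel edge length(s) in mm; a scalar (isotropic) or a
#'   length-3 vector.
#' @param origin_mm Optional length-3 vector: coordinates of the center of the
#'   first voxel. Defaults to centering the grid on isocenter.
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(64, 64, 48), 3)
#' range(grid_axis_mm(g, 1))
#' @export
grid3d <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid.shape must be three positive voxel counts")
  voxel <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("grid.voxel_size_mm must be positive")
  if (is.null(origin_mm)) origin_mm <- -(shape - 1) / 2 * voxel
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("grid.origin_mm must be a finite 3-vector")
  lo <- origin_mm - voxel / 2
  hi <- origin_mm + (shape - 0.5) * voxel
  if (any(lo > 0) || any(hi < 0))
    stop("isocenter (0,0,0) must lie inside the grid extent")
  structure(list(shape = shape, voxel_size_mm = voxel, origin_mm = origin_mm),
            class = "grid3d")
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid A [grid3d()].
#' @param axis Axis index (1 = x, 2 = y, 3 = z).
#' @return Numeric vector of voxel-center coordinates in mm.
#' @export
grid_axis_mm <- function(grid, axis) {
  stopifnot(inherits(grid, "grid3d"), axis %in% 1:3)
  grid$origin_mm[axis] +
    (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$voxel_size_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

check_mask <- function(mask, grid, what = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), as.integer(grid$shape)))
    stop(sprintf("%s must be a logical array matching the grid shape", what))
  invisible(mask)
}
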
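#' Write a volume to NIfTI-1 with grid geometry
#'
#' The affine encodes the voxel size and the isocenter-referenced origin of
#' the [grid3d()] frame, so volumes re-read with [read_nifti_volume()]
#' restore their grid.
#'
#' @param arr 3D numeric/logical array matching `grid`.
#' @param grid A [grid3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(arr, grid, path) {
  stopifnot(inherits(grid, "grid3d"))
  if (!identical(dim(arr), as.integer(grid$shape)))
    stop("array shape must match grid")
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti_volume()]
#'
#' @param path NIfTI file path.
#' @return List with `arr` (3D array) and `grid` ([grid3d()]).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  grid <- grid3d(dim(img), diag(aff)[1:3], aff[1:3, 4])
  list(arr = array(as.numeric(img), dim(img)), grid = grid)
}

#' Write a wrapped acquisition as NIfTI phase + magnitude volumes
#'
#' @param acq A [wrapped_acquisition()].
#' @param prefix Output path prefix; writes `<prefix>_phase.nii.gz` and
#'   `<prefix>_magnitude.nii.gz`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_acquisition_nifti <- function(acq, prefix) {
  stopifnot(inherits(acq, "wrapped_acquisition"))
  p <- paste0(prefix, c("_phase.nii.gz", "_magnitude.nii.gz"))
  write_nifti_volume(acq$phase_rad, acq$grid, p[1])
  write_nifti_volume(acq$magnitude, acq$grid, p[2])
  invisible(p)
}

#' Read a wrapped acquisition from NIfTI phase + magnitude volumes
#'
#' @param prefix Path prefix used by [write_acquisition_nifti()].
#' @param delta_te_s Echo-time spacing of the acquisition (not stored in
#'   NIfTI headers).
#' @return A [wrapped_acquisition()].
#' @export
read_acquisition_nifti <- function(prefix, delta_te_s) {
  ph <- read_nifti_volume(paste0(prefix, "_phase.nii.gz"))
  mg <- read_nifti_volume(paste0(prefix, "_magnitude.nii.gz"))
  ph$arr[ph$arr <= -pi] <- pi
  wrapped_acquisition(ph$arr, mg$arr, delta_te_s, ph$grid)
}
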
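#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} returning plain R arrays. Voxel
#' dimensions (mm) are stored in the header on write.
#'
#' @param path File path (`.nii` / `.nii.gz`).
#' @return For `read_volume`, a numeric array (3D or 4D).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "pixdim") <- RNifti::pixdim(img)
  a
}

#' @param vol Numeric 3D/4D array.
#' @param voxel_mm Voxel dimensions, mm.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  attr(vol, "pixdim") <- c(voxel_mm, rep(1, length(dim(vol)) - 3))
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), path)
  invisible(path)
}

#' Write a binary mask as uint8 NIfTI
#'
#' @param mask Logical/binary 3D array.
#' @param path File path.
#' @param voxel_mm Voxel dimensions, mm.
#' @export
write_mask <- function(mask, path, voxel_mm = c(1, 1, 1)) {
  m <- array(as.integer(mask > 0), dim(mask))
  attr(m, "pixdim") <- voxel_mm
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  invisible(path)
}

#' Write an ROI signal curve as TSV
#'
#' Columns `ti2_ms dm n_voxels roi slice`, tab-separated.
#'
#' @param curve A [roi_signal_curve()].
#' @param path File path.
#' @export
write_roi_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_curve
#' @export
read_roi_curve <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  roi_signal_curve(df$ti2_ms, df$dm, df$n_voxels,
                   roi = df$roi[1], slice = df$slice[1])
}
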
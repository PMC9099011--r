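#' Read a NIfTI volume
#'
#' NIfTI is accepted as a first-class alternative to DICOM series; the
#' array axes are taken as (row, col, slice) and the orientation header is
#' not interpreted further.
#'
#' @param path a .nii or .nii.gz file.
#' @return A \linkS4class{VoxelVolume}.
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(img)), " dimensions")
  arr <- array(as.vector(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  sp[!is.finite(sp) | sp <= 0] <- 1
  VoxelVolume(arr, spacing = sp)
}

#' Write a VoxelVolume as NIfTI
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeNiftiVolume <- function(volume, path) {
  img <- RNifti::asNifti(intensities(volume))
  RNifti::pixdim(img) <- spacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI label map
#'
#' @param path a .nii or .nii.gz file of integer labels.
#' @return A \linkS4class{LabelMap}.
#' @export
readNiftiLabels <- function(path) {
  img <- RNifti::readNifti(path)
  LabelMap(array(as.integer(round(as.vector(img))), dim = dim(img)))
}

#' Write a LabelMap as NIfTI
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param path output path.
#' @param spacing voxel spacing in mm.
#' @return \code{path}, invisibly.
#' @export
writeNiftiLabels <- function(labelmap, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(labels3d(labelmap))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
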
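# NIfTI-1 input/output.  Grid geometry round-trips through the sform
# affine: index-to-physical p = origin + orientation %*% (spacing * index),
# exactly the NIfTI voxel-to-world convention.

gridToAffine <- function(grid) {
  A <- diag(4)
  A[1:3, 1:3] <- grid@orientation %*% diag(grid@spacing)
  A[1:3, 4] <- grid@origin
  A
}

affineToGrid <- function(A, dim) {
  L <- A[1:3, 1:3]
  spacing <- sqrt(colSums(L^2))
  volumeGrid(dim, spacing, A[1:3, 4], sweep(L, 2L, spacing, "/"))
}

#' Read a NIfTI volume as a ScalarVolume
#' @param path .nii or .nii.gz file
#' @return a \linkS4class{ScalarVolume}
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  A <- RNifti::xform(img)
  vals <- array(as.numeric(img), dim(img)[1:3])
  scalarVolume(vals, affineToGrid(unclass(A), dim(vals)))
}

#' Read a NIfTI label volume as a BinaryMask
#' @param path .nii or .nii.gz file holding a 0/1 (or thresholdable) volume
#' @param organLabel organ name to attach
#' @param threshold voxels strictly above this value are foreground
#' @return a \linkS4class{BinaryMask}
#' @export
readMask <- function(path, organLabel = "organ", threshold = 0.5) {
  v <- readVolume(path)
  binaryMask(v@values > threshold, v@grid, organLabel)
}

writeNiftiArray <- function(values, grid, path, datatype = "float") {
  img <- RNifti::asNifti(values)
  img <- RNifti::`pixdim<-`(img, grid@spacing)
  A <- structure(gridToAffine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, A)
  img <- RNifti::`qform<-`(img, A)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a ScalarVolume to NIfTI
#' @param volume a \linkS4class{ScalarVolume}
#' @param path output .nii or .nii.gz path
#' @return invisibly, the path written
#' @export
writeVolume <- function(volume, path)
  writeNiftiArray(volume@values, volume@grid, path, "float")

#' Write a BinaryMask to NIfTI (uint8 label volume)
#' @param mask a \linkS4class{BinaryMask}
#' @param path output .nii or .nii.gz path
#' @return invisibly, the path written
#' @export
writeMask <- function(mask, path)
  writeNiftiArray(mask@values, mask@grid, path, "uint8")

#' Write a ProbabilityMap to NIfTI (float32)
#' @param map a \linkS4class{ProbabilityMap}
#' @param path output .nii or .nii.gz path
#' @return invisibly, the path written
#' @export
writeProbabilityMap <- function(map, path)
  writeNiftiArray(map@w, map@grid, path, "float")
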
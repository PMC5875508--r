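# Distance transforms and mask morphology.  All distances are true
# Euclidean distances in mm, honouring anisotropic voxel spacing, so a
# "1 cm margin" is isotropic regardless of the grid.

#' Squared Euclidean distance (mm^2) to a feature voxel set
#' @param feature logical/0-1 3D array marking feature voxels
#' @param spacing mm triple
#' @return 3D array of squared distances to the nearest feature voxel centre
#' @export
distanceTransformSq <- function(feature, spacing) {
  if (!any(feature)) stop("feature set is empty", call. = FALSE)
  array(.cpp_edt_sq(as.logical(feature), dim(feature), as.numeric(spacing)),
        dim(feature))
}

#' Dilate a mask by a physical margin
#'
#' Every voxel whose Euclidean distance (mm) to the input foreground is at
#' most \code{marginMm} becomes foreground; the metric is truly Euclidean
#' (not a cubic structuring element), so the margin is isotropic on
#' anisotropic grids.  Used to expand atlas organ masks with the 1 cm
#' registration-metric margin.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @param marginMm nonnegative margin in mm
#' @return the dilated \linkS4class{BinaryMask}
#' @export
dilateMask <- function(mask, marginMm) {
  stopifnot(marginMm >= 0)
  if (sum(mask@values) == 0) {
    warning("dilateMask: empty input mask returned unchanged")
    return(mask)
  }
  if (marginMm == 0) return(mask)
  dsq <- distanceTransformSq(mask@values > 0, mask@grid@spacing)
  binaryMask(dsq <= marginMm^2 + 1e-9, mask@grid, mask@organLabel)
}

#' Erode a mask by a physical margin
#' @param mask a \linkS4class{BinaryMask}
#' @param marginMm nonnegative margin in mm
#' @return the eroded \linkS4class{BinaryMask} (may be empty)
#' @export
erodeMask <- function(mask, marginMm) {
  stopifnot(marginMm >= 0)
  if (marginMm == 0 || sum(mask@values) == 0) return(mask)
  if (all(mask@values > 0)) return(mask)
  dsq <- distanceTransformSq(mask@values == 0, mask@grid@spacing)
  binaryMask(mask@values > 0 & dsq > marginMm^2 + 1e-9, mask@grid,
             mask@organLabel)
}

#' Signed Euclidean distance field of a mask
#'
#' Negative inside, positive outside, zero crossing on the mask boundary;
#' the standard level-set initialisation.  Values are distances in mm to
#' the nearest voxel centre across the interface.
#'
#' @param mask a \linkS4class{BinaryMask} with at least one foreground and
#'   one background voxel
#' @return a \linkS4class{LevelSetField}
#' @export
signedDistance <- function(mask) {
  fg <- mask@values > 0
  if (!any(fg) || all(fg))
    stop("signed distance undefined: mask has no interface", call. = FALSE)
  h <- mask@grid@spacing
  dOut <- sqrt(distanceTransformSq(fg, h))
  dIn <- sqrt(distanceTransformSq(!fg, h))
  phi <- dOut
  phi[fg] <- -dIn[fg]
  levelSetField(phi, mask@grid)
}

#' Label the 26-connected components of a mask
#' @param mask a \linkS4class{BinaryMask}
#' @return integer 3D array of component labels (0 = background)
#' @export
labelComponents <- function(mask) {
  array(.cpp_label26(mask@values > 0, mask@grid@dim), mask@grid@dim)
}

#' Keep only the largest 26-connected component of a mask
#' @param mask a \linkS4class{BinaryMask}
#' @return a \linkS4class{BinaryMask} containing the largest component
#' @export
largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  binaryMask(lab == keep, mask@grid, mask@organLabel)
}
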
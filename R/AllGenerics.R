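#' @import methods
#' @importFrom stats optim rnorm runif median quantile sd setNames
#' @importFrom utils head tail modifyList
NULL

#' Voxel dimensions of an object's grid
#' @param x an object carrying a \linkS4class{VolumeGrid}
#' @return integer triple of voxels per axis
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel spacing in millimetres
#' @param x an object carrying a \linkS4class{VolumeGrid}
#' @return numeric triple, mm per voxel along each axis
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' Physical origin of the first voxel centre (mm)
#' @param x an object carrying a \linkS4class{VolumeGrid}
#' @return numeric triple, mm
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Direction matrix of the grid axes
#' @param x an object carrying a \linkS4class{VolumeGrid}
#' @return 3 x 3 orthonormal matrix, columns are axis directions
#' @export
setGeneric("gridOrientation", function(x) standardGeneric("gridOrientation"))

#' Extract the geometry of an image object
#' @param x a volume, mask, probability map or level-set field
#' @return the \linkS4class{VolumeGrid} the object lives on
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' Voxel values of an image object
#' @param x a volume, mask, probability map or level-set field
#' @return a 3D array of voxel values
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Organ label attached to a mask
#' @param x a \linkS4class{BinaryMask}
#' @return a length-one character string
#' @export
setGeneric("organLabel", function(x) standardGeneric("organLabel"))

#' Map physical points through a spatial transform
#'
#' Transforms map fixed-image (patient) physical points into moving-image
#' (atlas) physical space: the resampling convention, so that a warped atlas
#' image can be evaluated on the patient grid.
#'
#' @param transform a \linkS4class{SpatialTransform}
#' @param points n x 3 matrix of physical coordinates (mm)
#' @return n x 3 matrix of mapped physical coordinates (mm)
#' @export
setGeneric("transformPoints", function(transform, points)
  standardGeneric("transformPoints"))

#' Resample an image onto a target grid through a transform
#'
#' @param x a \linkS4class{ScalarVolume} or \linkS4class{BinaryMask}
#' @param target the \linkS4class{VolumeGrid} to resample onto
#' @param transform a \linkS4class{SpatialTransform} mapping target physical
#'   points into the source image's physical space (identity by default)
#' @param interpolation \code{"linear"} or \code{"nearest"}; masks are always
#'   resampled nearest-neighbour
#' @param fill value assigned outside the source field of view
#'   (default -1000 HU for volumes, 0 for masks)
#' @return an object of the same class as \code{x}, defined on \code{target}
#' @export
setGeneric("resample", function(x, target, transform = identityTransform(),
                                interpolation = c("linear", "nearest"),
                                fill = NULL)
  standardGeneric("resample"))

#' Dice overlap coefficient between two binary masks
#' @param a,b \linkS4class{BinaryMask} objects on the same grid
#' @return 2|A∩B| / (|A|+|B|), in [0, 1]
#' @export
setGeneric("dice", function(a, b) standardGeneric("dice"))

#' Symmetric mean surface distance between two masks (mm)
#' @param a,b nonempty \linkS4class{BinaryMask} objects on the same grid
#' @param symmetric average both directed means (default); otherwise a-to-b
#' @return mean boundary-to-boundary distance in mm
#' @export
setGeneric("meanSurfaceDistance", function(a, b, symmetric = TRUE)
  standardGeneric("meanSurfaceDistance"))

#' Hausdorff (maximum surface) distance between two masks (mm)
#' @param a,b nonempty \linkS4class{BinaryMask} objects on the same grid
#' @return maximum boundary-to-boundary distance in mm
#' @export
setGeneric("hausdorff", function(a, b) standardGeneric("hausdorff"))
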
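#' ScalarVolume: a 3D scalar image with physical geometry
#'
#' Carries Hounsfield-unit CT intensities (or any scalar field) on a
#' \linkS4class{VolumeGrid}.
#'
#' @slot grid the \linkS4class{VolumeGrid}
#' @slot values 3D numeric array, finite, dim equal to grid dim
#' @export
setClass("ScalarVolume",
  representation(grid = "VolumeGrid", values = "array"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dim)))
      return("values array dim must equal grid dim")
    if (any(!is.finite(object@values)))
      return("values must be finite")
    TRUE
  })

#' BinaryMask: a per-organ segmentation on a grid
#'
#' @slot grid the \linkS4class{VolumeGrid}
#' @slot values 3D array of 0/1
#' @slot organLabel organ name
#' @export
setClass("BinaryMask",
  representation(grid = "VolumeGrid", values = "array",
                 organLabel = "character"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dim)))
      return("values array dim must equal grid dim")
    if (!all(object@values %in% c(0, 1)))
      return("mask values must be 0 or 1")
    if (length(object@organLabel) != 1L)
      return("organLabel must be a single string")
    TRUE
  })

#' LevelSetField: signed implicit surface on a grid
#'
#' The zero level set is the segmentation boundary; the field is negative
#' inside the object and positive outside, in physical mm.
#'
#' @slot grid the \linkS4class{VolumeGrid}
#' @slot phi 3D numeric array of signed values (mm)
#' @export
setClass("LevelSetField",
  representation(grid = "VolumeGrid", phi = "array"),
  validity = function(object) {
    if (!identical(dim(object@phi), as.integer(object@grid@dim)))
      return("phi array dim must equal grid dim")
    if (any(!is.finite(object@phi)))
      return("phi must be finite")
    TRUE
  })

#' ProbabilityMap: voxelwise posterior organ probability
#'
#' Output of STAPLE fusion: for each voxel the posterior probability that it
#' lies inside the organ, together with the global prior used and the number
#' of EM iterations run.
#'
#' @slot grid the \linkS4class{VolumeGrid}
#' @slot w 3D array of probabilities in [0, 1]
#' @slot prior global foreground prior used by the EM
#' @slot iterationsRun EM iterations executed
#' @export
setClass("ProbabilityMap",
  representation(grid = "VolumeGrid", w = "array", prior = "numeric",
                 iterationsRun = "integer"),
  validity = function(object) {
    if (!identical(dim(object@w), as.integer(object@grid@dim)))
      return("w array dim must equal grid dim")
    if (any(object@w < 0 | object@w > 1, na.rm = TRUE))
      return("w must lie in [0, 1]")
    TRUE
  })

#' Construct a ScalarVolume
#' @param values 3D numeric array
#' @param grid a \linkS4class{VolumeGrid}; defaults to unit spacing
#' @return a \linkS4class{ScalarVolume}
#' @export
scalarVolume <- function(values, grid = volumeGrid(dim(values))) {
  storage.mode(values) <- "double"
  new("ScalarVolume", grid = grid, values = values)
}

#' Construct a BinaryMask
#' @param values 3D array coercible to 0/1 (logical accepted)
#' @param grid a \linkS4class{VolumeGrid}; defaults to unit spacing
#' @param organLabel organ name string
#' @return a \linkS4class{BinaryMask}
#' @export
binaryMask <- function(values, grid = volumeGrid(dim(values)),
                       organLabel = "organ") {
  v <- array(as.numeric(values != 0), dim = dim(values))
  new("BinaryMask", grid = grid, values = v, organLabel = organLabel)
}

#' Construct a LevelSetField
#' @param phi 3D numeric array, signed, negative inside
#' @param grid a \linkS4class{VolumeGrid}
#' @return a \linkS4class{LevelSetField}
#' @export
levelSetField <- function(phi, grid = volumeGrid(dim(phi))) {
  storage.mode(phi) <- "double"
  new("LevelSetField", grid = grid, phi = phi)
}

#' @rdname imageGrid-methods
#' @name imageGrid-methods
#' @aliases imageGrid,ScalarVolume-method
#' @export
setMethod("imageGrid", "ScalarVolume", function(x) x@grid)
#' @rdname imageGrid-methods
#' @export
setMethod("imageGrid", "BinaryMask", function(x) x@grid)
#' @rdname imageGrid-methods
#' @export
setMethod("imageGrid", "LevelSetField", function(x) x@grid)
#' @rdname imageGrid-methods
#' @export
setMethod("imageGrid", "ProbabilityMap", function(x) x@grid)

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "ScalarVolume", function(x) x@values)
#' @rdname voxelValues
#' @export
setMethod("voxelValues", "BinaryMask", function(x) x@values)
#' @rdname voxelValues
#' @export
setMethod("voxelValues", "LevelSetField", function(x) x@phi)
#' @rdname voxelValues
#' @export
setMethod("voxelValues", "ProbabilityMap", function(x) x@w)

#' @rdname organLabel
#' @export
setMethod("organLabel", "BinaryMask", function(x) x@organLabel)

#' @rdname gridDim
#' @export
setMethod("gridDim", "ScalarVolume", function(x) x@grid@dim)
#' @rdname gridDim
#' @export
setMethod("gridDim", "BinaryMask", function(x) x@grid@dim)
#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "ScalarVolume", function(x) x@grid@spacing)
#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "BinaryMask", function(x) x@grid@spacing)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "ScalarVolume", function(x) x@grid@origin)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "BinaryMask", function(x) x@grid@origin)
#' @rdname gridOrientation
#' @export
setMethod("gridOrientation", "ScalarVolume", function(x) x@grid@orientation)
#' @rdname gridOrientation
#' @export
setMethod("gridOrientation", "BinaryMask", function(x) x@grid@orientation)

setMethod("show", "ScalarVolume", function(object) {
  v <- object@values
  cat("ScalarVolume", paste(dim(v), collapse = " x "),
      sprintf("| range [%.1f, %.1f]\n", min(v), max(v)))
  show(object@grid)
})

setMethod("show", "BinaryMask", function(object) {
  n <- sum(object@values)
  cat(sprintf("BinaryMask '%s': %d foreground voxels (%.2f ml)\n",
              object@organLabel, as.integer(n),
              n * prod(object@grid@spacing) / 1000))
  show(object@grid)
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf(
    "ProbabilityMap: prior %.3f, %d EM iterations, %d voxels with w >= 0.5\n",
    object@prior, object@iterationsRun, sum(object@w >= 0.5)))
  show(object@grid)
})

setMethod("show", "LevelSetField", function(object) {
  cat(sprintf("LevelSetField: %d voxels inside (phi < 0)\n",
              sum(object@phi < 0)))
  show(object@grid)
})

#' Number of foreground voxels in a mask
#' @param mask a \linkS4class{BinaryMask}
#' @return integer voxel count
#' @export
maskVoxelCount <- function(mask) as.integer(sum(mask@values))

#' Mask volume in millilitres
#' @param mask a \linkS4class{BinaryMask}
#' @return volume in ml (voxel count times voxel volume)
#' @export
maskVolumeMl <- function(mask)
  sum(mask@values) * prod(mask@grid@spacing) / 1000

stopifnotSameGrid <- function(a, b) {
  if (!sameGrid(imageGrid(a), imageGrid(b)))
    stop("objects are defined on different grids", call. = FALSE)
}
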
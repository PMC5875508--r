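#' VolumeGrid: physical geometry of a 3D image
#'
#' A \code{VolumeGrid} fixes the sampling lattice of a volume: voxels per
#' axis, spacing in mm, physical position of the first voxel centre, and an
#' orthonormal direction matrix whose columns are the physical directions of
#' the array axes.  The index-to-physical map is
#' \code{p = origin + orientation \%*\% (spacing * index)} with 0-based
#' indices, so voxel (0,0,0) sits exactly at \code{origin}.
#'
#' @slot dim integer triple, voxels per axis
#' @slot spacing numeric triple, mm (all > 0)
#' @slot origin numeric triple, mm
#' @slot orientation 3 x 3 orthonormal direction matrix
#' @export
setClass("VolumeGrid",
  representation(dim = "integer", spacing = "numeric",
                 origin = "numeric", orientation = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msg <- c(msg, "dim must be a positive integer triple")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing components must be finite and > 0")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be a finite mm triple")
    o <- object@orientation
    if (!all(dim(o) == c(3L, 3L)) || any(!is.finite(o)))
      msg <- c(msg, "orientation must be a finite 3x3 matrix")
    else {
      if (max(abs(crossprod(o) - diag(3))) > 1e-8)
        msg <- c(msg, "orientation must be orthonormal")
      if (abs(abs(det(o)) - 1) > 1e-8)
        msg <- c(msg, "orientation must have |det| = 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a VolumeGrid
#'
#' @param dim voxels per axis (integer triple)
#' @param spacing mm per voxel (default 1 mm isotropic)
#' @param origin physical position of voxel (0,0,0), mm
#' @param orientation 3 x 3 direction matrix (default identity)
#' @return a \linkS4class{VolumeGrid}
#' @examples
#' g <- volumeGrid(c(64, 64, 64), spacing = c(2.5, 2.5, 2.5))
#' gridSpacing(g)
#' @export
volumeGrid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = diag(3)) {
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeGrid", dim = as.integer(dim), spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' @rdname gridDim
#' @export
setMethod("gridDim", "VolumeGrid", function(x) x@dim)
#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "VolumeGrid", function(x) x@origin)
#' @rdname gridOrientation
#' @export
setMethod("gridOrientation", "VolumeGrid", function(x) x@orientation)

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dim, collapse = " x "),
      "voxels, spacing", paste(signif(object@spacing, 4), collapse = "/"),
      "mm\n  origin (", paste(signif(object@origin, 4), collapse = ", "),
      ") mm\n")
})

#' Convert 0-based voxel indices to physical mm coordinates
#' @param grid a \linkS4class{VolumeGrid}
#' @param idx n x 3 matrix of 0-based (possibly continuous) voxel indices
#' @return n x 3 matrix of physical coordinates (mm)
#' @export
indexToPhysical <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx, 2L, grid@spacing, "*") %*% t(grid@orientation) +
    rep(1, nrow(idx)) %o% grid@origin
}

#' Convert physical mm coordinates to continuous 0-based voxel indices
#' @param grid a \linkS4class{VolumeGrid}
#' @param pts n x 3 matrix of physical coordinates (mm)
#' @return n x 3 matrix of continuous 0-based voxel indices
#' @export
physicalToIndex <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  rel <- pts - rep(1, nrow(pts)) %o% grid@origin
  sweep(rel %*% grid@orientation, 2L, grid@spacing, "/")
}

#' Physical coordinates of every voxel centre
#' @param grid a \linkS4class{VolumeGrid}
#' @return (prod(dim)) x 3 matrix of mm coordinates, column-major voxel order
#' @export
gridPoints <- function(grid) {
  d <- grid@dim
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  indexToPhysical(grid, idx)
}

#' Physical centre of the image domain
#' @param grid a \linkS4class{VolumeGrid}
#' @return mm triple at the centre of the voxel lattice
#' @export
gridCenter <- function(grid) {
  drop(indexToPhysical(grid, matrix((grid@dim - 1) / 2, 1L)))
}

#' Physical extent of the image along each grid axis
#' @param grid a \linkS4class{VolumeGrid}
#' @return mm triple, (dim - 1) * spacing
#' @export
gridExtent <- function(grid) (grid@dim - 1) * grid@spacing

sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dim, b@dim) &&
    max(abs(a@spacing - b@spacing)) < tol &&
    max(abs(a@origin - b@origin)) < tol &&
    max(abs(a@orientation - b@orientation)) < tol
}
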
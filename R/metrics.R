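# Segmentation agreement measures.  Surfaces are voxel-face based: a
# boundary voxel is a foreground voxel with at least one background face
# neighbour (volume edges count as background); distances are exact
# Euclidean distances between boundary voxel centres in mm.

#' @rdname dice
#' @export
setMethod("dice", signature("BinaryMask", "BinaryMask"), function(a, b) {
  stopifnotSameGrid(a, b)
  na <- sum(a@values)
  nb <- sum(b@values)
  if (na + nb == 0)
    stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(a@values * b@values) / (na + nb)
})

# Boundary voxels: foreground with a background face neighbour (6-conn);
# the volume edge counts as background.
boundaryVoxels <- function(mask) {
  v <- mask@values > 0
  d <- dim(v)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- function(di, dj, dk)
    padded[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
  interior <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  v & !interior
}

surfaceDistances <- function(a, b) {
  stopifnotSameGrid(a, b)
  if (sum(a@values) == 0 || sum(b@values) == 0)
    stop("surface distance undefined for an empty mask", call. = FALSE)
  h <- a@grid@spacing
  bA <- boundaryVoxels(a)
  bB <- boundaryVoxels(b)
  dToB <- sqrt(distanceTransformSq(bB, h))
  dToA <- sqrt(distanceTransformSq(bA, h))
  list(aToB = dToB[bA], bToA = dToA[bB])
}

#' @rdname meanSurfaceDistance
#' @export
setMethod("meanSurfaceDistance", signature("BinaryMask", "BinaryMask"),
          function(a, b, symmetric = TRUE) {
  sd <- surfaceDistances(a, b)
  if (symmetric) (mean(sd$aToB) + mean(sd$bToA)) / 2 else mean(sd$aToB)
})

#' @rdname hausdorff
#' @export
setMethod("hausdorff", signature("BinaryMask", "BinaryMask"),
          function(a, b) {
  sd <- surfaceDistances(a, b)
  max(max(sd$aToB), max(sd$bToA))
})

#' Full overlap report between two masks
#'
#' @param a,b \linkS4class{BinaryMask}s on the same grid (conventionally
#'   automated vs manual/reference)
#' @return list with \code{dice}, \code{meanSurfaceDistanceMm},
#'   \code{hausdorffMm}, \code{volumeAMl}, \code{volumeBMl}
#' @export
overlapReport <- function(a, b) {
  list(dice = dice(a, b),
       meanSurfaceDistanceMm = meanSurfaceDistance(a, b),
       hausdorffMm = hausdorff(a, b),
       volumeAMl = maskVolumeMl(a),
       volumeBMl = maskVolumeMl(b))
}
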
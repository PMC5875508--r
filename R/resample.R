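resampleValues <- function(sourceGrid, sourceValues, target, transform,
                           nearest, fill) {
  pts <- gridPoints(target)
  mapped <- transformPoints(transform, pts)
  idx <- physicalToIndex(sourceGrid, mapped)
  v <- .cpp_interp3(as.numeric(sourceValues), sourceGrid@dim, idx,
                    fill, nearest)
  array(v, target@dim)
}

#' @describeIn resample CT volumes default to linear interpolation and a
#'   -1000 HU (air) out-of-field fill.
#' @export
setMethod("resample", "ScalarVolume",
          function(x, target, transform = identityTransform(),
                   interpolation = c("linear", "nearest"), fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- -1000
  vals <- resampleValues(x@grid, x@values, target, transform,
                         interpolation == "nearest", fill)
  scalarVolume(vals, target)
})

#' @describeIn resample masks are always resampled nearest-neighbour (so
#'   they stay binary) with a 0 (background) fill.
#' @export
setMethod("resample", "BinaryMask",
          function(x, target, transform = identityTransform(),
                   interpolation = c("linear", "nearest"), fill = NULL) {
  if (is.null(fill)) fill <- 0
  vals <- resampleValues(x@grid, x@values, target, transform, TRUE, fill)
  binaryMask(vals, target, organLabel = x@organLabel)
})

#' Warp atlas organ masks onto the patient grid
#'
#' Applies the registration result to every atlas mask with
#' nearest-neighbour resampling, preserving organ labels.
#'
#' @param atlasMasks list of \linkS4class{BinaryMask}s on the atlas grid
#' @param transform transform mapping patient points to atlas space
#' @param patientGrid the target \linkS4class{VolumeGrid}
#' @return list of \linkS4class{BinaryMask}s on the patient grid
#' @export
warpAtlasLabels <- function(atlasMasks, transform, patientGrid) {
  lapply(atlasMasks, resample, target = patientGrid, transform = transform)
}
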
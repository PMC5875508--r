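# Per-structure refinement: three steps, each feeding the next.
# 1. extract the organ HU interval from the fused (STAPLE) shape by
#    multi-level Otsu analysis;
# 2. adapt the shape to that interval with a threshold level set;
# 3. smooth and recover weak-edge regions with a geodesic level set.

#' Per-organ refinement configuration
#'
#' @param bins Otsu histogram bins (default 125)
#' @param classes Otsu classes (default 4)
#' @param thresholdParams \linkS4class{LevelSetParams} of the threshold
#'   stage (propagation 1, curvature 0.5, 500 iterations)
#' @param geodesicParams \linkS4class{LevelSetParams} of the geodesic
#'   stage (propagation 1, curvature 3, advection 1, 30 iterations)
#' @param smoothingSigmaMm edge-image smoothing of the geodesic stage
#' @param speedForm threshold-stage speed: \code{"ramp"} or \code{"binary"}
#' @param histogramDilationMm margin added to the seed before the HU
#'   histogram is built, so that neighbouring tissue forms contrast
#'   classes even when the fused shape hugs the organ tightly
#' @return a list of refinement settings
#' @export
refineConfig <- function(bins = 125, classes = 4,
                         thresholdParams = levelSetParams(1, 0.5,
                                                          maxIter = 500),
                         geodesicParams = levelSetParams(1, 3, 1,
                                                         maxIter = 30,
                                                         rmsTol = 1e-5),
                         smoothingSigmaMm = 1.5,
                         speedForm = "ramp",
                         histogramDilationMm = 5) {
  list(bins = bins, classes = classes, thresholdParams = thresholdParams,
       geodesicParams = geodesicParams,
       smoothingSigmaMm = smoothingSigmaMm, speedForm = speedForm,
       histogramDilationMm = histogramDilationMm)
}

#' Refine one organ estimate against the patient CT
#'
#' Chains \code{\link{otsuHuInterval}}, \code{\link{thresholdLevelSet}} and
#' \code{\link{geodesicLevelSet}}.  When the in-mask histogram is too
#' uniform for Otsu analysis (poor contrast), the interval falls back to
#' the raw in-mask HU range with a warning and the \code{fallback} flag.
#'
#' @param seed nonempty \linkS4class{BinaryMask}, the thresholded STAPLE map
#' @param volume the patient \linkS4class{ScalarVolume}
#' @param config settings from \code{\link{refineConfig}}
#' @return the refined \linkS4class{BinaryMask}; the
#'   \code{"diagnostics"} attribute records the HU interval, iterations and
#'   volume after every step, and the fallback flag
#' @export
refineStructure <- function(seed, volume, config = refineConfig()) {
  stopifnotSameGrid(seed, volume)
  if (sum(seed@values) == 0)
    stop("refineStructure: empty seed mask", call. = FALSE)
  fallback <- FALSE
  histMask <- if (config$histogramDilationMm > 0)
    dilateMask(seed, config$histogramDilationMm) else seed
  interval <- tryCatch(
    otsuHuInterval(volume, histMask, config$bins, config$classes),
    atlasseg_degenerate_histogram = function(e) {
      warning("refineStructure: degenerate histogram for '",
              seed@organLabel, "', falling back to in-mask HU range")
      fallback <<- TRUE
      r <- range(volume@values[seed@values > 0])
      new("HUInterval", lower = r[1], upper = r[2], thresholds = numeric(),
          classHistogram = numeric(), classOfVoxel = integer(),
          largestClass = 1L, fallback = TRUE)
    })
  phi0 <- signedDistance(seed)
  # on the degenerate-interval fallback the steps are guarded: a vanished
  # interface keeps the previous stage's shape (with a warning) so the
  # contract of returning a mask holds; otherwise step errors propagate
  guard <- function(expr, prev) {
    if (!fallback && !interval@fallback) return(expr)
    tryCatch(expr, atlasseg_interface_vanished = function(e) {
      warning("refineStructure: ", conditionMessage(e),
              "; keeping the previous shape")
      prev
    })
  }
  phi1 <- guard(thresholdLevelSet(phi0, volume, interval,
                                  params = config$thresholdParams,
                                  speedForm = config$speedForm), phi0)
  phi2 <- guard(geodesicLevelSet(phi1, volume,
                                 params = config$geodesicParams,
                                 smoothingSigmaMm = config$smoothingSigmaMm),
                phi1)
  out <- levelSetToMask(phi2, seed@organLabel)
  diag <- list(
    organ = seed@organLabel,
    interval = c(lower = interval@lower, upper = interval@upper),
    fallback_threshold = fallback || interval@fallback,
    iterations = c(threshold = attr(phi1, "iterations"),
                   geodesic = attr(phi2, "iterations")),
    volumeMl = c(seed = maskVolumeMl(seed),
                 threshold = sum(phi1@phi < 0) *
                   prod(volume@grid@spacing) / 1000,
                 geodesic = maskVolumeMl(out)))
  attr(out, "diagnostics") <- diag
  out
}
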
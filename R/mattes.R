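# Mattes mutual information: sampled joint-histogram estimator with a
# zero-order (box) Parzen window on the fixed intensities and a cubic
# B-spline window on the moving intensities.  Suited to CT-to-CT matching
# under differing contrast and HU calibration because only the statistical
# dependence of the intensities matters, not their scale.

#' Configuration for the Mattes MI metric
#'
#' @slot bins number of histogram bins per axis (>= 2)
#' @slot samplingFraction fraction of candidate voxels sampled, in (0, 1]
#' @slot fixedMask optional \linkS4class{BinaryMask} restricting where fixed
#'   samples are drawn
#' @slot seed RNG seed for the (per-run fixed) sample subset
#' @export
setClass("MIMetricConfig",
  representation(bins = "integer", samplingFraction = "numeric",
                 fixedMask = "ANY", seed = "integer"),
  validity = function(object) {
    if (object@bins < 2L) return("bins must be >= 2")
    if (object@samplingFraction <= 0 || object@samplingFraction > 1)
      return("samplingFraction must be in (0, 1]")
    TRUE
  })

#' Construct an MIMetricConfig
#' @param bins histogram bins (default 20, the affine-stage setting)
#' @param samplingFraction voxel sampling fraction (default 0.5)
#' @param fixedMask optional \linkS4class{BinaryMask} for sample locations
#' @param seed sampling seed (default 1)
#' @return an \linkS4class{MIMetricConfig}
#' @export
miMetricConfig <- function(bins = 20, samplingFraction = 0.5,
                           fixedMask = NULL, seed = 1) {
  new("MIMetricConfig", bins = as.integer(bins),
      samplingFraction = as.numeric(samplingFraction),
      fixedMask = fixedMask, seed = as.integer(seed))
}

# Run code with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Seeded sample of fixed-image voxels: returns physical points and
# intensities.  The subset is drawn once per run for determinism.
miSampleFixed <- function(fixed, cfg) {
  d <- fixed@grid@dim
  n <- prod(d)
  cand <- if (!is.null(cfg@fixedMask)) which(cfg@fixedMask@values > 0)
          else seq_len(n)
  ns <- max(2L, round(cfg@samplingFraction * length(cand)))
  sel <- if (ns >= length(cand)) cand
         else withSeed(cfg@seed, sort(sample(cand, ns)))
  sel0 <- sel - 1L
  i <- sel0 %% d[1]
  j <- (sel0 %/% d[1]) %% d[2]
  k <- sel0 %/% (d[1] * d[2])
  pts <- indexToPhysical(fixed@grid, cbind(i, j, k))
  list(points = pts, values = fixed@values[sel], index = sel)
}

# Precompute everything about a fixed/moving pair that does not depend on
# the transform: sampled fixed points, fixed bin indices, moving-intensity
# binning, and log-space scratch.
miPrepare <- function(fixed, moving, cfg, movingMask = NULL,
                      movingGradient = NULL) {
  smp <- miSampleFixed(fixed, cfg)
  nb <- cfg@bins
  fr <- range(fixed@values)
  if (diff(fr) == 0) stop("fixed image is constant", call. = FALSE)
  fBin <- pmin(floor((smp$values - fr[1]) / (diff(fr) / nb)), nb - 1)
  mr <- range(moving@values)
  if (diff(mr) == 0) stop("moving image is constant", call. = FALSE)
  mWidth <- diff(mr) / (nb - 4)          # 2-bin pad so the cubic window fits
  list(points = smp$points, fBin = as.integer(fBin), bins = nb,
       movingMin = mr[1], movingWidth = mWidth,
       movingGrid = moving@grid, movingValues = as.numeric(moving@values),
       movingMask = movingMask, movingGradient = movingGradient,
       nSamples = nrow(smp$points))
}

# Evaluate negated MI (and optionally its derivative w.r.t. each sample's
# continuous moving-bin coordinate) at mapped physical points.
miEvaluateAt <- function(prep, mapped, wantDeriv = FALSE) {
  nb <- prep$bins
  idx <- physicalToIndex(prep$movingGrid, mapped)
  mv <- .cpp_interp3(prep$movingValues, prep$movingGrid@dim, idx,
                     NA_real_, FALSE)
  valid <- !is.na(mv)
  if (!is.null(prep$movingMask)) {
    inMask <- .cpp_interp3(prep$movingMask, prep$movingGrid@dim, idx,
                           0, TRUE)
    valid <- valid & inMask > 0.5
  }
  nValid <- sum(valid)
  if (nValid < nb * nb)
    stop(errorCondition(
      sprintf("too few valid metric samples (%d < %d)", nValid, nb * nb),
      class = "atlasseg_metric_degenerate"))
  vi <- which(valid)
  mhat <- (mv[vi] - prep$movingMin) / prep$movingWidth + 1.5
  mhat <- pmin(pmax(mhat, 1), nb - 2 - 1e-9)
  fb <- prep$fBin[vi]
  res <- .cpp_mattes(fb, mhat, nb, wantDeriv)
  out <- list(value = res$value, nValid = nValid, valid = valid)
  if (wantDeriv) {
    d <- numeric(prep$nSamples)
    d[vi] <- res$dmhat
    out$dPerSample <- d          # w.r.t. continuous bin coordinate
    out$dValueScale <- 1 / prep$movingWidth
  }
  out
}

#' Mattes mutual-information metric between two volumes
#'
#' Returns the negated mutual information (lower is better) of the sampled
#' joint intensity distribution of \code{fixed} and \code{moving} under a
#' transform, estimated with a zero-order Parzen window on the fixed axis
#' and a cubic B-spline window on the moving axis.  Fixed samples whose
#' mapped point falls outside the moving image domain (or outside the
#' moving-space mask, when one is supplied) are ignored.
#'
#' @param fixed,moving \linkS4class{ScalarVolume}s
#' @param transform a \linkS4class{SpatialTransform} mapping fixed points
#'   into moving space (identity by default)
#' @param cfg an \linkS4class{MIMetricConfig}
#' @param movingMask optional \linkS4class{BinaryMask} in moving space;
#'   samples mapping outside it are discarded
#' @return negated mutual information in nats (scalar)
#' @export
mattesMI <- function(fixed, moving, transform = identityTransform(),
                     cfg = miMetricConfig(), movingMask = NULL) {
  prep <- miPrepare(fixed, moving, cfg,
                    movingMask = if (!is.null(movingMask))
                      movingMask@values else NULL)
  mapped <- transformPoints(transform, prep$points)
  miEvaluateAt(prep, mapped)$value
}
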
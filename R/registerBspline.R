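# Masked multi-resolution cubic B-spline deformable registration.  The
# control lattice is refined over four stages (node spacing 100 / 73 / 40 /
# 20 mm by default, the geometric schedule between the 10 cm and 2 cm
# endpoints); each stage is optimised by L-BFGS against the Mattes MI
# metric with an analytic gradient obtained by chaining the Parzen-window
# derivative, the moving-image spatial gradient, and the (stage-constant)
# sparse B-spline weight matrix of the fixed sample points.

#' Configuration defaults for B-spline deformable registration
#'
#' @param stagesMm control-node spacing schedule in mm, coarse to fine
#' @param bins MI histogram bins for the deformable stages
#' @param samplingFraction fraction of candidate fixed voxels sampled
#' @param seed metric sampling seed
#' @param maskMarginMm dilation margin applied to the union of atlas organ
#'   masks before it gates the metric samples (the 1 cm relevance margin)
#' @param captureMarginMm extra margin for preselecting candidate samples,
#'   allowing for displacement during optimisation
#' @param stageMaxIter L-BFGS iteration cap per stage
#' @param gradientTol L-BFGS projected-gradient tolerance
#' @param lbfgsMemory L-BFGS history size
#' @param gradientSigmaMm smoothing of the moving image before its spatial
#'   gradient is taken for the metric derivative
#' @param pyramidSigmaFactor per-stage Gaussian smoothing of both images
#'   as a fraction of the stage's node spacing (the image half of the
#'   multi-resolution scheme); 0 disables the pyramid
#' @return a list of settings for \code{\link{registerBspline}}
#' @export
bsplineConfig <- function(stagesMm = c(100, 73, 40, 20), bins = 32,
                          samplingFraction = 1.0, seed = 1,
                          maskMarginMm = 10, captureMarginMm = 20,
                          stageMaxIter = 60, gradientTol = 1e-5,
                          lbfgsMemory = 5, gradientSigmaMm = NULL,
                          pyramidSigmaFactor = 0) {
  list(stagesMm = stagesMm, bins = bins,
       samplingFraction = samplingFraction, seed = seed,
       maskMarginMm = maskMarginMm, captureMarginMm = captureMarginMm,
       stageMaxIter = stageMaxIter, gradientTol = gradientTol,
       lbfgsMemory = lbfgsMemory, gradientSigmaMm = gradientSigmaMm,
       pyramidSigmaFactor = pyramidSigmaFactor)
}

# Union of organ masks as one mask on the moving grid.
maskUnion <- function(masks) {
  v <- Reduce(`+`, lapply(masks, voxelValues))
  binaryMask(v > 0, masks[[1]]@grid, "union")
}

#' Masked multi-resolution B-spline registration
#'
#' Starting from an affine initialisation, optimises a cubic B-spline
#' free-form deformation of the patient domain so that the composite
#' \code{affine(x + u(x))} maximises mutual information with the moving
#' (atlas) image.  Metric samples are gated by the union of the atlas
#' organ masks dilated by \code{maskMarginMm}: a fixed sample contributes
#' only while its mapped point falls inside that mask, so irrelevant
#' regions (artifacts, table, unrelated anatomy) cannot drag the match.
#'
#' @param fixed the patient \linkS4class{ScalarVolume}
#' @param moving the atlas \linkS4class{ScalarVolume}
#' @param init an \linkS4class{AffineTransform} from
#'   \code{\link{registerAffine}}
#' @param movingOrganMasks list of \linkS4class{BinaryMask}s on the moving
#'   grid (the atlas presegmentations)
#' @param cfg settings from \code{\link{bsplineConfig}}
#' @return a \linkS4class{CompositeTransform} \code{[affine, ffd]} mapping
#'   patient points to atlas points, with a \code{"stageMetrics"} attribute
#' @export
registerBspline <- function(fixed, moving, init, movingOrganMasks,
                            cfg = bsplineConfig()) {
  stopifnot(is(init, "AffineTransform"), length(movingOrganMasks) >= 1)
  union <- maskUnion(movingOrganMasks)
  gate <- dilateMask(union, cfg$maskMarginMm)
  capture <- dilateMask(gate, cfg$captureMarginMm)

  # candidate fixed samples: voxels whose affine image lands in the capture
  # region (gate + slack for deformation growth during optimisation)
  micfg <- miMetricConfig(cfg$bins, cfg$samplingFraction, seed = cfg$seed)
  smp <- miSampleFixed(fixed, micfg)
  aff <- transformPoints(init, smp$points)
  inCapture <- .cpp_interp3(as.numeric(capture@values), capture@grid@dim,
                            physicalToIndex(capture@grid, aff), 0, TRUE)
  keep <- inCapture > 0.5
  if (sum(keep) < cfg$bins^2)
    stop(errorCondition(
      sprintf(paste0("mask-coverage error: only %d fixed samples map into ",
                     "the dilated organ mask [%s]"), sum(keep),
              paste(vapply(movingOrganMasks, organLabel, ""),
                    collapse = ", ")),
      class = "atlasseg_mask_coverage"))

  gradSigma <- if (is.null(cfg$gradientSigmaMm))
    mean(moving@grid@spacing) / 2 else cfg$gradientSigmaMm
  keepIdx <- smp$index[keep]
  pts <- smp$points[keep, , drop = FALSE]
  A <- init@matrix
  ffd <- NULL
  stageMetrics <- numeric(0)
  for (s in seq_along(cfg$stagesMm)) {
    ffd <- if (is.null(ffd)) ffdLattice(fixed@grid, cfg$stagesMm[s])
           else ffdRefine(ffd, fixed@grid, cfg$stagesMm[s])
    # image half of the multi-resolution scheme: smooth both images at a
    # scale tied to the stage's control spacing
    sigmaS <- cfg$pyramidSigmaFactor * cfg$stagesMm[s]
    fixedS <- if (sigmaS > 0) gaussianSmooth(fixed, sigmaS) else fixed
    movingS <- if (sigmaS > 0) gaussianSmooth(moving, sigmaS) else moving
    movGrad <- gradientVolume(movingS, gradSigma)
    fr <- range(fixedS@values)
    mr <- range(movingS@values)
    prep <- list(points = pts,
                 fBin = as.integer(pmin(floor(
                   (fixedS@values[keepIdx] - fr[1]) /
                     (diff(fr) / cfg$bins)), cfg$bins - 1)),
                 bins = cfg$bins,
                 movingGrid = moving@grid,
                 movingValues = as.numeric(movingS@values),
                 movingMin = mr[1],
                 movingWidth = diff(mr) / (cfg$bins - 4),
                 movingMask = gate@values,
                 nSamples = length(keepIdx))
    W <- ffdWeightMatrix(ffd, pts)
    nNodes <- prod(ffd@nodeDim)
    evalAt <- function(theta, wantDeriv) {
      disp <- as.matrix(W %*% matrix(theta, nNodes, 3L))
      mapped <- transformPoints(init, pts + disp)
      miEvaluateAt(prep, mapped, wantDeriv = wantDeriv)
    }
    cache <- new.env(parent = emptyenv())
    fn <- function(theta) {
      r <- tryCatch(evalAt(theta, TRUE),
                    atlasseg_metric_degenerate = function(e) NULL)
      if (is.null(r)) return(1e6)
      assign("theta", theta, cache); assign("r", r, cache)
      r$value
    }
    gr <- function(theta) {
      r <- if (!is.null(cache$theta) && identical(cache$theta, theta))
        cache$r else tryCatch(evalAt(theta, TRUE),
                              atlasseg_metric_degenerate = function(e) NULL)
      if (is.null(r)) return(numeric(nNodes * 3L))
      s_i <- r$dPerSample * r$dValueScale   # d(-MI)/d(moving value); 0 if invalid
      disp <- as.matrix(W %*% matrix(theta, nNodes, 3L))
      mappedIdx <- physicalToIndex(prep$movingGrid,
                                   transformPoints(init, pts + disp))
      gm <- vapply(1:3, function(a)
        .cpp_interp3(as.numeric(movGrad[, , , a]), prep$movingGrid@dim,
                     mappedIdx, 0, FALSE), numeric(prep$nSamples))
      G <- (gm %*% A) * s_i
      as.numeric(as.matrix(Matrix::crossprod(W, G)))
    }
    theta0 <- as.numeric(ffd@coefficients)
    opt <- optim(theta0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$stageMaxIter,
                                pgtol = cfg$gradientTol,
                                lmm = cfg$lbfgsMemory, factr = 1e7))
    ffd@coefficients <- array(opt$par, c(ffd@nodeDim, 3L))
    stageMetrics <- c(stageMetrics, opt$value)
  }
  out <- compositeTransform(init, ffd)
  attr(out, "stageMetrics") <- stageMetrics
  out
}
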
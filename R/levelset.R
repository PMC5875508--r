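# Explicit dense level-set evolution with upwind propagation, central
# curvature, optional advection, CFL-bounded time steps and periodic
# signed-distance reinitialisation.  The field is evolved on a bounding
# box cropped around the initial interface for speed; the crop margin
# bounds how far the surface may travel.

#' LevelSetParams: weights and stopping rules for level-set evolution
#'
#' @slot propagationWeight weight of the image-driven expansion term
#' @slot curvatureWeight weight of the curvature (smoothing) term
#' @slot advectionWeight weight of the edge-attraction term (geodesic only)
#' @slot maxIter iteration cap (>= 1)
#' @slot rmsTol stop when the RMS change of phi over the interface band
#'   drops below this (mm)
#' @export
setClass("LevelSetParams",
  representation(propagationWeight = "numeric", curvatureWeight = "numeric",
                 advectionWeight = "numeric", maxIter = "integer",
                 rmsTol = "numeric"),
  validity = function(object) {
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    if (object@rmsTol <= 0) return("rmsTol must be > 0")
    TRUE
  })

#' Construct LevelSetParams
#' @param propagationWeight expansion weight (default 1)
#' @param curvatureWeight smoothing weight (default 0.5)
#' @param advectionWeight edge-attraction weight (default 0)
#' @param maxIter iteration cap (default 500)
#' @param rmsTol RMS-change stopping tolerance (default 1e-5)
#' @return a \linkS4class{LevelSetParams}
#' @export
levelSetParams <- function(propagationWeight = 1, curvatureWeight = 0.5,
                           advectionWeight = 0, maxIter = 500,
                           rmsTol = 1e-5) {
  new("LevelSetParams", propagationWeight = propagationWeight,
      curvatureWeight = curvatureWeight, advectionWeight = advectionWeight,
      maxIter = as.integer(maxIter), rmsTol = rmsTol)
}

# Crop box (index ranges) around the negative phase of phi plus a margin.
cropBox <- function(inside, d, marginVox) {
  ijk <- which(inside, arr.ind = TRUE)
  lo <- pmax(apply(ijk, 2, min) - marginVox, 1L)
  hi <- pmin(apply(ijk, 2, max) + marginVox, d)
  list(lo = lo, hi = hi)
}

cropArray <- function(a, box)
  a[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
    drop = FALSE]

# One-sided differences of a cropped field.
upwindTerms <- function(phi, h) {
  Dm <- Dp <- vector("list", 3L)
  for (a in 1:3) {
    Dm[[a]] <- (phi - shiftArray(phi, a, 1)) / h[a]   # backward
    Dp[[a]] <- (shiftArray(phi, a, -1) - phi) / h[a]  # forward
  }
  gPlus <- sqrt(pmax(Dm[[1]], 0)^2 + pmin(Dp[[1]], 0)^2 +
                pmax(Dm[[2]], 0)^2 + pmin(Dp[[2]], 0)^2 +
                pmax(Dm[[3]], 0)^2 + pmin(Dp[[3]], 0)^2)
  gMinus <- sqrt(pmin(Dm[[1]], 0)^2 + pmax(Dp[[1]], 0)^2 +
                 pmin(Dm[[2]], 0)^2 + pmax(Dp[[2]], 0)^2 +
                 pmin(Dm[[3]], 0)^2 + pmax(Dp[[3]], 0)^2)
  list(Dm = Dm, Dp = Dp, gPlus = gPlus, gMinus = gMinus)
}

# Mean curvature times |grad phi| (central differences), curvature clamped
# to the voxel scale for stability.
curvatureTerm <- function(phi, h) {
  px <- centralDiff(phi, 1, h[1]); py <- centralDiff(phi, 2, h[2])
  pz <- centralDiff(phi, 3, h[3])
  pxx <- (shiftArray(phi, 1, -1) - 2 * phi + shiftArray(phi, 1, 1)) / h[1]^2
  pyy <- (shiftArray(phi, 2, -1) - 2 * phi + shiftArray(phi, 2, 1)) / h[2]^2
  pzz <- (shiftArray(phi, 3, -1) - 2 * phi + shiftArray(phi, 3, 1)) / h[3]^2
  pxy <- centralDiff(centralDiff(phi, 1, h[1]), 2, h[2])
  pxz <- centralDiff(centralDiff(phi, 1, h[1]), 3, h[3])
  pyz <- centralDiff(centralDiff(phi, 2, h[2]), 3, h[3])
  g2 <- px^2 + py^2 + pz^2
  num <- pxx * (py^2 + pz^2) + pyy * (px^2 + pz^2) + pzz * (px^2 + py^2) -
    2 * (pxy * px * py + pxz * px * pz + pyz * py * pz)
  kap <- num / (g2^1.5 + 1e-12)
  kap <- pmin(pmax(kap, -1 / min(h)), 1 / min(h))
  kap * sqrt(g2)
}

# Core explicit solver.  propField: signed outward speed (dimensionless,
# |.| <= ~1); curvField: curvature weight field; advField: list of three
# velocity component arrays (mm^-1 scale) or NULL.
levelSetEvolveCore <- function(phi, h, propField, curvField, advField,
                               maxIter, rmsTol, reinitEvery, stepName,
                               cropIsFullGrid = TRUE) {
  maxP <- max(abs(propField))
  maxC <- max(curvField)
  maxA <- if (is.null(advField)) 0 else
    max(abs(advField[[1]]), abs(advField[[2]]), abs(advField[[3]]))
  # combined CFL rate: hyperbolic (propagation + advection) and parabolic
  # (curvature) contributions add
  rate <- (maxP + maxA * max(h)) / (0.45 * min(h)) +
    6 * maxC / min(h)^2
  dt <- 1 / max(rate, 1e-12)
  cap <- 6 * max(h)   # narrow-band clamp keeps far values from drifting
  phi <- pmin(pmax(phi, -cap), cap)
  iters <- 0L
  for (it in seq_len(maxIter)) {
    uw <- upwindTerms(phi, h)
    dphi <- -(pmax(propField, 0) * uw$gPlus + pmin(propField, 0) * uw$gMinus)
    if (maxC > 0) dphi <- dphi + curvField * curvatureTerm(phi, h)
    if (!is.null(advField)) {
      for (a in 1:3) {
        u <- advField[[a]]
        dphi <- dphi + pmax(u, 0) * uw$Dm[[a]] + pmin(u, 0) * uw$Dp[[a]]
      }
    }
    phiNew <- pmin(pmax(phi + dt * dphi, -cap), cap)
    rms <- sqrt(mean((phiNew - phi)^2))
    phi <- phiNew
    iters <- it
    inside <- phi < 0
    # no foreground left is a global loss of the interface; a fully
    # saturated crop only means the surface reached the crop boundary
    if (!any(inside) || (all(inside) && cropIsFullGrid))
      stop(errorCondition(
        sprintf("level-set interface vanished during %s", stepName),
        class = "atlasseg_interface_vanished"))
    if (rms < rmsTol) break
    if (it %% reinitEvery == 0L && it < maxIter) {
      dOut <- sqrt(distanceTransformSq(inside, h))
      dIn <- sqrt(distanceTransformSq(!inside, h))
      phi <- dOut
      phi[inside] <- -dIn[inside]
      phi <- pmin(pmax(phi, -cap), cap)
    }
  }
  list(phi = phi, iterations = iters, dt = dt)
}

# Run the solver on a crop of the full field and paste the result back.
levelSetEvolveCropped <- function(init, fields, params, reinitEvery,
                                  stepName, marginVox = 16L) {
  grid <- init@grid
  d <- grid@dim
  inside <- init@phi < 0
  if (!any(inside) || all(inside))
    stop(errorCondition(
      sprintf("level-set init has no interface (%s)", stepName),
      class = "atlasseg_interface_vanished"))
  box <- cropBox(inside, d, marginVox)
  phi <- cropArray(init@phi, box)
  cropped <- lapply(fields$arrays, cropArray, box = box)
  names(cropped) <- names(fields$arrays)
  adv <- if (is.null(fields$adv)) NULL else
    lapply(fields$adv, cropArray, box = box)
  res <- levelSetEvolveCore(phi, grid@spacing, cropped$prop, cropped$curv,
                            adv, params@maxIter, params@rmsTol,
                            reinitEvery, stepName,
                            cropIsFullGrid = all(box$lo == 1L) &&
                              all(box$hi == d))
  out <- init@phi
  out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    res$phi
  structure(levelSetField(out, grid),
            iterations = res$iterations, dt = res$dt)
}

#' Threshold-driven level-set evolution
#'
#' Evolves \eqn{\partial\phi/\partial t = -\alpha S |\nabla\phi| +
#' \beta \kappa |\nabla\phi|} where the speed \eqn{S} is positive
#' (expansion) where the image intensity lies inside the HU interval and
#' negative outside: the piecewise-linear ramp
#' \eqn{S = \min(I - lower, upper - I)} clipped to \eqn{\pm} half the
#' interval width and normalised by it, so the weights are scale-free.
#' Upwind differencing for propagation, central for curvature, CFL-bounded
#' steps, signed-distance reinitialisation every \code{reinitEvery}
#' iterations.
#'
#' @param init a signed-distance-like \linkS4class{LevelSetField}
#' @param volume the CT \linkS4class{ScalarVolume}
#' @param interval an \linkS4class{HUInterval} or numeric c(lower, upper)
#' @param params \linkS4class{LevelSetParams}; defaults propagation 1,
#'   curvature 0.5, 500 iterations
#' @param speedForm \code{"ramp"} (clipped linear, default) or
#'   \code{"binary"} (hard +1/-1)
#' @param reinitEvery reinitialisation period in iterations
#' @return the evolved \linkS4class{LevelSetField} with attributes
#'   \code{"iterations"} and \code{"dt"}
#' @export
thresholdLevelSet <- function(init, volume, interval,
                              params = levelSetParams(1, 0.5,
                                                      maxIter = 500),
                              speedForm = c("ramp", "binary"),
                              reinitEvery = 50L) {
  speedForm <- match.arg(speedForm)
  stopifnotSameGrid(init, volume)
  if (is(interval, "HUInterval"))
    interval <- c(interval@lower, interval@upper)
  stopifnot(interval[1] <= interval[2])
  I <- volume@values
  edge <- (interval[2] - interval[1]) / 2
  S <- pmin(I - interval[1], interval[2] - I)
  S <- if (speedForm == "ramp" && edge > 1e-9)
    pmin(pmax(S / edge, -1), 1)
  else  # binary speed; also the zero-width (degenerate interval) fallback
    ifelse(I >= interval[1] & I <= interval[2], 1, -1)
  fields <- list(arrays = list(
    prop = params@propagationWeight * S,
    curv = array(params@curvatureWeight, dim(I))))
  levelSetEvolveCropped(init, fields, params, reinitEvery,
                        "threshold level set")
}

# Edge-stopping function of the geodesic stage: inverse gradient of the
# smoothed image, linearly rescaled to [0, 1] (flattest voxel -> 1,
# strongest edge -> 0).  An image with no contrast at all has no edges to
# seek: NULL is returned and the caller falls back to pure curvature flow.
edgeFunction <- function(volume, sigmaMm) {
  gm <- gradientMagnitude(volume, sigmaMm)@values
  g <- 1 / (1 + gm)
  r <- range(g)
  if (diff(r) < 1e-9) return(NULL)
  (g - r[1]) / diff(r)
}

#' Geodesic active-contour level-set smoothing
#'
#' Evolves \eqn{\partial\phi/\partial t = -\alpha g |\nabla\phi| +
#' \beta g \kappa |\nabla\phi| + \gamma \nabla g \cdot \nabla\phi} where
#' \eqn{g} is the inverse-gradient edge image of the Gaussian-smoothed CT,
#' rescaled to [0, 1].  The balloon term grows the shape across weak
#' (e.g. motion-blurred) edges while the heavy curvature weight and the
#' short iteration cap keep it from leaking into neighbouring structures.
#'
#' @param init a signed-distance-like \linkS4class{LevelSetField}
#' @param volume the CT \linkS4class{ScalarVolume}
#' @param params \linkS4class{LevelSetParams}; defaults propagation 1,
#'   curvature 3, advection 1, 30 iterations, RMS tolerance 1e-5
#' @param smoothingSigmaMm Gaussian sigma for the edge image (default 1.5)
#' @param reinitEvery reinitialisation period in iterations
#' @return the evolved \linkS4class{LevelSetField} with attributes
#'   \code{"iterations"} and \code{"dt"}
#' @export
geodesicLevelSet <- function(init, volume,
                             params = levelSetParams(1, 3, 1,
                                                     maxIter = 30,
                                                     rmsTol = 1e-5),
                             smoothingSigmaMm = 1.5, reinitEvery = 50L) {
  stopifnotSameGrid(init, volume)
  g <- edgeFunction(volume, smoothingSigmaMm)
  if (is.null(g)) {
    # contrast-free image: no edges to seek, so the image force (balloon
    # and advection) vanishes and only the curvature flow acts
    d <- volume@grid@dim
    fields <- list(arrays = list(
      prop = array(0, d),
      curv = array(params@curvatureWeight, d)), adv = NULL)
    return(levelSetEvolveCropped(init, fields, params, reinitEvery,
                                 "geodesic level set"))
  }
  adv <- NULL
  if (params@advectionWeight != 0) {
    gv <- scalarVolume(g, volume@grid)
    gg <- gradientVolume(gv, 0)
    adv <- lapply(1:3, function(a) params@advectionWeight * gg[, , , a])
  }
  fields <- list(arrays = list(
    prop = params@propagationWeight * g,
    curv = params@curvatureWeight * g), adv = adv)
  levelSetEvolveCropped(init, fields, params, reinitEvery,
                        "geodesic level set")
}

#' Convert the zero-sublevel set of a field to a BinaryMask
#' @param field a \linkS4class{LevelSetField}
#' @param organLabel organ name for the mask
#' @return a \linkS4class{BinaryMask} of voxels with phi < 0
#' @export
levelSetToMask <- function(field, organLabel = "organ")
  binaryMask(field@phi < 0, field@grid, organLabel)
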
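# Two-phase affine initialisation: centre-of-mass matching, then a
# regular-step gradient-descent search over translations only (posture and
# table-position differences dominate), then over all twelve affine
# parameters with per-parameter scales.

#' Configuration defaults for affine registration
#'
#' @param bins MI histogram bins
#' @param samplingFraction fraction of fixed voxels sampled for the metric
#' @param seed metric sampling seed
#' @param phase1Iter iterations of the translation-only phase
#' @param phase2Iter iterations of the full 12-parameter phase
#' @param initialStepMm initial optimizer step (translation-equivalent mm)
#' @param relaxation step shrink factor on a gradient direction reversal
#' @param minStepMm step underflow threshold ending a phase
#' @param gradientDeltaMm finite-difference probe (scaled units)
#' @return a list of settings for \code{\link{registerAffine}}
#' @export
affineConfig <- function(bins = 20, samplingFraction = 0.5, seed = 1,
                         phase1Iter = 30, phase2Iter = 30,
                         initialStepMm = 2, relaxation = 0.5,
                         minStepMm = 1e-3, gradientDeltaMm = 0.1) {
  list(bins = bins, samplingFraction = samplingFraction, seed = seed,
       phase1Iter = phase1Iter, phase2Iter = phase2Iter,
       initialStepMm = initialStepMm, relaxation = relaxation,
       minStepMm = minStepMm, gradientDeltaMm = gradientDeltaMm)
}

# Intensity centre of mass in physical coordinates; CT values are shifted
# by +1000 so air carries (almost) no weight.
intensityCentroid <- function(volume) {
  w <- pmax(as.numeric(volume@values) + 1000, 0)
  pts <- gridPoints(volume@grid)
  colSums(pts * w) / sum(w)
}

# theta (scaled parameters) -> AffineTransform.  The linear part is
# parameterised as rotations * scales * shears so that each physical degree
# of freedom is one optimizer coordinate; angle/log-scale/shear parameters
# are scaled by the fixed-image half-extent so one optimizer unit moves a
# boundary point about as far as a 1 mm translation.
thetaToAffine <- function(theta, center, matScale) {
  a <- theta[1:3] / matScale   # Euler angles (rad)
  s <- exp(theta[4:6] / matScale)
  h <- theta[7:9] / matScale
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]),
                 0, -sin(a[1]), cos(a[1])), 3L)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3L)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3L)
  Sh <- matrix(c(1, 0, 0, h[1], 1, 0, h[2], h[3], 1), 3L)
  M <- Rz %*% Ry %*% Rx %*% diag(s) %*% Sh
  affineTransform(M, theta[10:12], center)
}

# Regular-step gradient descent: a trial step of the current length is
# taken along the unit gradient; improving steps are accepted and the step
# grows slightly, worsening steps are rejected and the step relaxes, so the
# increments stay proportional to the changes in the cost function.
regularStepDescent <- function(fn, theta, active, maxIter, step0, relax,
                               minStep, delta, growth = 1.2,
                               maxStep = 10) {
  cur <- fn(theta)
  best <- list(theta = theta, value = cur)
  step <- step0
  for (it in seq_len(maxIter)) {
    g <- numeric(length(theta))
    for (j in which(active)) {
      tp <- theta
      tp[j] <- tp[j] + delta
      g[j] <- (fn(tp) - cur) / delta
    }
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    repeat {
      cand <- theta - step * g / gn
      cv <- fn(cand)
      if (cv < cur) {
        theta <- cand
        cur <- cv
        step <- min(step * growth, maxStep)
        break
      }
      step <- step * relax
      if (step < minStep) break
    }
    if (step < minStep) break
    if (cur < best$value) best <- list(theta = theta, value = cur)
  }
  list(theta = best$theta, value = best$value, finalValue = cur)
}

#' Affine registration of a moving volume onto a fixed volume
#'
#' Initialises by matching the intensity centres of mass, then minimises
#' the negated Mattes mutual information with a regular-step gradient
#' descent in two phases: translations only, then the full affine
#' (shear, scaling, rotation and translation) with per-parameter scales.
#'
#' @param fixed,moving nonconstant \linkS4class{ScalarVolume}s
#' @param cfg settings from \code{\link{affineConfig}}
#' @return an \linkS4class{AffineTransform} mapping fixed physical points
#'   to moving physical points; the attribute \code{"diverged"} is TRUE if
#'   the final step was worse than the best visited (best is returned)
#' @export
registerAffine <- function(fixed, moving, cfg = affineConfig()) {
  if (diff(range(fixed@values)) == 0 || diff(range(moving@values)) == 0)
    stop("registerAffine: constant input volume", call. = FALSE)
  micfg <- miMetricConfig(cfg$bins, cfg$samplingFraction, seed = cfg$seed)
  prep <- miPrepare(fixed, moving, micfg)
  center <- gridCenter(fixed@grid)
  matScale <- max(gridExtent(fixed@grid)) / 2
  t0 <- intensityCentroid(moving) - intensityCentroid(fixed)
  theta <- c(rep(0, 9), t0)
  fn <- function(th) {
    tr <- thetaToAffine(th, center, matScale)
    tryCatch(miEvaluateAt(prep, transformPoints(tr, prep$points))$value,
             atlasseg_metric_degenerate = function(e) 1e6)
  }
  p1 <- regularStepDescent(fn, theta, active = c(rep(FALSE, 9), rep(TRUE, 3)),
                           maxIter = cfg$phase1Iter,
                           step0 = cfg$initialStepMm, relax = cfg$relaxation,
                           minStep = cfg$minStepMm,
                           delta = cfg$gradientDeltaMm)
  p2 <- regularStepDescent(fn, p1$theta, active = rep(TRUE, 12),
                           maxIter = cfg$phase2Iter,
                           step0 = cfg$initialStepMm, relax = cfg$relaxation,
                           minStep = cfg$minStepMm,
                           delta = cfg$gradientDeltaMm)
  diverged <- p2$finalValue > p2$value + 1e-12
  if (diverged)
    warning("registerAffine: optimizer ended above its best value; ",
            "returning best-so-far")
  out <- thetaToAffine(p2$theta, center, matScale)
  attr(out, "diverged") <- diverged
  attr(out, "metricValue") <- p2$value
  out
}
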
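# Synthetic CT phantom generator: stylised thoraco-abdominal anatomy with
# known ground truth, plus deformed, reposed, intensity-remapped "atlas"
# variants whose true patient-to-atlas transforms are recorded.  The
# geometry is deliberately stylised; what it reproduces is the statistical
# structure of the real problem: several soft-tissue organs of similar HU
# adjacent to each other, high-contrast lungs and bone, smooth
# inter-subject deformation, posture changes, HU-calibration differences
# and noise.

#' Specification of a synthetic CT phantom
#'
#' @param gridDim voxels per axis (default 64)
#' @param spacingMm voxel size in mm (default 2.5, the scanner protocol
#'   voxel size emulated here)
#' @param organs list of organ definitions
#'   \code{list(label, center, semiAxes, hu, huJitter)} (mm, HU); defaults
#'   to lungs, liver, spleen and kidneys laid out inside a body ellipsoid
#' @param bodyHU soft-tissue background HU (default 20)
#' @param lungHU lung HU (default -800; lungs defined in \code{organs})
#' @param boneHU vertebral-column HU (default 700)
#' @param noiseSigmaHU patient image Gaussian noise sd (default 8)
#' @param deformationMaxMm bound on the random atlas deformation (default 8)
#' @param deformationNodeMm control spacing of the random deformation
#'   lattice (default 55; deliberately off the registration schedule)
#' @param rotationRangeDeg posture rotation range about z (default 5)
#' @param translationRangeMm posture translation range per axis (default 8)
#' @param remapSlopeRange,remapOffsetRange monotone intensity recalibration
#'   a*v + b drawn per atlas
#' @param nAtlases number of atlas variants (default 3)
#' @param seed master seed; every random draw derives from it
#' @return a classed list describing the phantom
#' @export
phantomSpec <- function(gridDim = 64, spacingMm = 2.5,
                        organs = standardOrgans(),
                        bodyHU = 20, lungHU = -800, boneHU = 700,
                        noiseSigmaHU = 8, deformationMaxMm = 8,
                        deformationNodeMm = 55, rotationRangeDeg = 5,
                        translationRangeMm = 8,
                        remapSlopeRange = c(0.92, 1.08),
                        remapOffsetRange = c(-40, 40),
                        nAtlases = 3, seed = 1) {
  spec <- list(gridDim = gridDim, spacingMm = spacingMm, organs = organs,
               bodyHU = bodyHU, lungHU = lungHU, boneHU = boneHU,
               noiseSigmaHU = noiseSigmaHU,
               deformationMaxMm = deformationMaxMm,
               deformationNodeMm = deformationNodeMm,
               rotationRangeDeg = rotationRangeDeg,
               translationRangeMm = translationRangeMm,
               remapSlopeRange = remapSlopeRange,
               remapOffsetRange = remapOffsetRange,
               nAtlases = nAtlases, seed = seed)
  class(spec) <- "PhantomSpec"
  spec
}

#' Default stylised organ layout (mm, inside a 160 mm cube domain)
#' @param lungHU,liverHU,spleenHU,kidneyHU mean organ HU values
#' @return list of organ definitions for \code{\link{phantomSpec}}
#' @export
standardOrgans <- function(lungHU = -800, liverHU = 60, spleenHU = 55,
                           kidneyHU = 45) {
  list(
    list(label = "lung_l", center = c(47, 70, 106),
         semiAxes = c(19, 23, 31), hu = lungHU, huJitter = 10),
    list(label = "lung_r", center = c(113, 70, 106),
         semiAxes = c(19, 23, 31), hu = lungHU, huJitter = 10),
    list(label = "liver", center = c(56, 84, 56),
         semiAxes = c(29, 23, 21), hu = liverHU, huJitter = 4),
    list(label = "spleen", center = c(114, 88, 58),
         semiAxes = c(13, 12, 14), hu = spleenHU, huJitter = 4),
    list(label = "kidney_l", center = c(52, 113, 31),
         semiAxes = c(10, 9, 13), hu = kidneyHU, huJitter = 4),
    list(label = "kidney_r", center = c(104, 113, 31),
         semiAxes = c(10, 9, 13), hu = kidneyHU, huJitter = 4))
}

ellipsoidArray <- function(grid, center, semiAxes) {
  d <- grid@dim
  ax <- lapply(1:3, function(a) {
    x <- grid@origin[a] + grid@spacing[a] * (seq_len(d[a]) - 1)
    ((x - center[a]) / semiAxes[a])^2
  })
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1
}

rasterizeBase <- function(spec, grid, jitters) {
  d <- grid@dim
  v <- array(-1000, d)
  ctr <- gridCenter(grid)
  body <- ellipsoidArray(grid, c(ctr[1], ctr[2], ctr[3]),
                         c(0.44, 0.41, 0.55) * gridExtent(grid) +
                           c(1, 1, 40))
  v[body] <- spec$bodyHU
  # vertebral column: z-axis capsule, background anatomy (not a target)
  x <- grid@origin[1] + grid@spacing[1] * (seq_len(d[1]) - 1)
  y <- grid@origin[2] + grid@spacing[2] * (seq_len(d[2]) - 1)
  r2 <- outer((x - ctr[1])^2, (y - 35 - ctr[2])^2 * 0 +
                (y - (ctr[2] + 35))^2, "+")
  spine <- array(rep(r2 <= 9^2, d[3]), d) & body
  v[spine] <- spec$boneHU
  masks <- list()
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    m <- ellipsoidArray(grid, o$center, o$semiAxes)
    v[m] <- o$hu + jitters[i]
    masks[[o$label]] <- binaryMask(m, grid, o$label)
  }
  list(volume = scalarVolume(v, grid), masks = masks)
}

validatePhantomSpec <- function(spec, masks) {
  labs <- names(masks)
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (sum(masks[[i]]@values * masks[[j]]@values) > 0)
      stop(sprintf("phantom organs '%s' and '%s' overlap", labs[i], labs[j]),
           call. = FALSE)
  }
  minRadius <- min(vapply(spec$organs,
                          function(o) min(o$semiAxes), numeric(1)))
  if (spec$deformationMaxMm >= minRadius)
    stop("deformationMaxMm must be below the smallest organ radius",
         call. = FALSE)
  invisible(TRUE)
}

# Random smooth displacement on a coarse lattice, max |u| bounded.
randomFFD <- function(grid, nodeMm, maxMm) {
  ffd <- ffdLattice(grid, nodeMm)
  nd <- ffd@nodeDim
  amp <- maxMm / sqrt(3)
  ffd@coefficients <- array(runif(prod(nd) * 3, -amp, amp), c(nd, 3L))
  ffd
}

# Numerically invert y = rigid(x + u(x)) for all voxels of `grid` by
# fixed-point iteration x <- rigid^-1(y) - u(x); u is a contraction (its
# gradient is well below 1 by the deformation bound), so a few iterations
# reach sub-0.01 mm accuracy.  u is interpolated from a precomputed
# separable evaluation of the spline on the grid for speed.
invertWarpPoints <- function(rigid, ffd, grid, iterations = 8) {
  y <- gridPoints(grid)
  Rinv <- solve(rigid@matrix)
  base <- sweep(sweep(y, 2L, rigid@center + rigid@translation, "-") %*%
                  t(Rinv), 2L, rigid@center, "+")
  U <- ffdDisplacementField(ffd, grid)
  x <- base
  for (i in seq_len(iterations)) {
    xi <- physicalToIndex(grid, x)
    u <- vapply(1:3, function(a)
      .cpp_interp3(as.numeric(U[, , , a]), grid@dim, xi, 0, FALSE),
      numeric(nrow(x)))
    x <- base - u
  }
  x
}

#' Generate a synthetic patient plus deformed atlas set
#'
#' The patient is the stylised base anatomy plus Gaussian noise; each atlas
#' is the base anatomy seen through a recorded true transform
#' (random smooth deformation composed with a rigid posture change) and a
#' monotone intensity recalibration.  The recorded transform maps patient
#' physical points to atlas physical points, so warping an atlas mask
#' through it reproduces the patient ground truth up to resampling.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @return a classed list: \code{patient} (\linkS4class{ScalarVolume}),
#'   \code{truth} (named list of \linkS4class{BinaryMask}s),
#'   \code{atlases} (each with \code{volume}, \code{masks},
#'   \code{transform}), \code{base}, and \code{spec}
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- volumeGrid(rep(spec$gridDim, 3), rep(spec$spacingMm, 3))
  withSeed(spec$seed, {
    jitters <- rnorm(length(spec$organs),
                     sd = vapply(spec$organs, function(o) o$huJitter,
                                 numeric(1)) / 2)
    base <- rasterizeBase(spec, grid, jitters)
    validatePhantomSpec(spec, base$masks)
    patient <- scalarVolume(
      base$volume@values +
        array(rnorm(prod(grid@dim), sd = spec$noiseSigmaHU), grid@dim),
      grid)
    atlases <- vector("list", spec$nAtlases)
    for (k in seq_len(spec$nAtlases)) {
      ang <- runif(1, -spec$rotationRangeDeg, spec$rotationRangeDeg)
      tr <- runif(3, -spec$translationRangeMm, spec$translationRangeMm)
      rigid <- rotationTransform(ang, axis = 3, center = gridCenter(grid),
                                 translation = tr)
      ffd <- randomFFD(grid, spec$deformationNodeMm, spec$deformationMaxMm)
      trueTransform <- compositeTransform(rigid, ffd)
      x <- invertWarpPoints(rigid, ffd, grid)
      xi <- physicalToIndex(grid, x)
      a <- runif(1, spec$remapSlopeRange[1], spec$remapSlopeRange[2])
      b <- runif(1, spec$remapOffsetRange[1], spec$remapOffsetRange[2])
      av <- a * .cpp_interp3(as.numeric(base$volume@values), grid@dim, xi,
                             -1000, FALSE) + b
      masks <- lapply(base$masks, function(m) {
        mv <- .cpp_interp3(as.numeric(m@values), grid@dim, xi, 0, TRUE)
        binaryMask(array(mv, grid@dim), grid, m@organLabel)
      })
      atlases[[k]] <- list(volume = scalarVolume(array(av, grid@dim), grid),
                           masks = masks, transform = trueTransform)
    }
    out <- list(patient = patient, truth = base$masks, atlases = atlases,
                base = base$volume, spec = spec)
    class(out) <- "PhantomCase"
    out
  })
}

#' Standard segmentation configuration for phantom validation
#'
#' Identical to \code{\link{segmentationConfig}} except for the
#' per-structure Otsu settings, which state each phantom organ's tissue
#' multiplicity: the class count must match the number of tissue modes the
#' histogram mask actually contains, otherwise the split subdivides the
#' organ mode itself — the degenerate case the interval extraction is
#' documented to be vulnerable to.  The phantom's organs are internally
#' homogeneous against one soft-tissue background (two modes; the liver
#' additionally abuts lung, three), whereas the clinical default of four
#' classes reflects fused shapes spanning several tissue groups.  The
#' histogram shell is one voxel (2.5 mm) so neighbouring tissue forms the
#' contrast class without swallowing more remote structures.  Choosing
#' these settings per structure is the customisation the refinement scheme
#' is built around.
#'
#' @param seed master seed passed through to the configuration
#' @param ... further arguments to \code{\link{segmentationConfig}}
#' @return a \code{SegmentationConfig}
#' @export
phantomSegmentationConfig <- function(seed = 1, ...) {
  segmentationConfig(
    refine = refineConfig(classes = 2, histogramDilationMm = 2.5),
    refineOverrides = list(liver = list(classes = 3)),
    seed = seed, ...)
}

#' Insert a named confounder into a phantom patient
#'
#' Deterministically modifies the patient volume only (never the atlases),
#' recording the altered region for targeted assertions.
#'
#' \describe{
#'   \item{artifact_blob}{a 1500 HU pellet (implant-like) in soft tissue
#'     outside every organ}
#'   \item{blurred_pole}{the superior pole of the left kidney gets shifted
#'     HU and locally blurred boundaries, emulating respiratory motion}
#'   \item{attached_blob}{a stomach-like blob of different HU attached to
#'     the spleen surface}
#'   \item{missing_organ}{the left lung is removed from the patient
#'     (filled with soft tissue)}
#' }
#'
#' @param case a \code{PhantomCase} from \code{\link{generatePhantom}}
#' @param kind one of \code{"artifact_blob"}, \code{"blurred_pole"},
#'   \code{"attached_blob"}, \code{"missing_organ"}
#' @return the modified \code{PhantomCase}; \code{$confounder} holds the
#'   kind and the affected region as a \linkS4class{BinaryMask}
#' @export
addConfounder <- function(case, kind = c("artifact_blob", "blurred_pole",
                                         "attached_blob",
                                         "missing_organ")) {
  kind <- match.arg(kind)
  grid <- case$patient@grid
  v <- case$patient@values
  organOf <- function(label) {
    m <- case$truth[[label]]
    if (is.null(m)) stop("confounder '", kind, "' needs organ '", label,
                         "' in the phantom", call. = FALSE)
    m
  }
  huOf <- function(label) {
    o <- Filter(function(o) o$label == label, case$spec$organs)[[1]]
    o$hu
  }
  if (kind == "artifact_blob") {
    region <- ellipsoidArray(grid, c(80, 38, 80), c(7, 7, 7))
    v[region] <- 1500
  } else if (kind == "blurred_pole") {
    kid <- organOf("kidney_l")
    o <- Filter(function(o) o$label == "kidney_l", case$spec$organs)[[1]]
    zIdx <- physicalToIndex(grid, matrix(c(0, 0, o$center[3] +
                                             0.45 * o$semiAxes[3]), 1))[3]
    d <- grid@dim
    zPlane <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    region <- kid@values > 0 & zPlane > zIdx + 1
    v[region] <- huOf("kidney_l") + 30
    # local blur of the pole neighbourhood
    box <- cropBox(region, d, 4L)
    sub <- scalarVolume(cropArray(v, box),
                        volumeGrid(dim(cropArray(v, box)),
                                   grid@spacing))
    sub <- gaussianSmooth(sub, 2.5 * mean(grid@spacing))
    v[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
      sub@values
  } else if (kind == "attached_blob") {
    spl <- organOf("spleen")
    o <- Filter(function(o) o$label == "spleen", case$spec$organs)[[1]]
    blobCenter <- o$center + c(0, o$semiAxes[2] + 6, 0)
    blob <- ellipsoidArray(grid, blobCenter, c(10, 10, 10))
    region <- blob & !(spl@values > 0)
    v[region] <- 110
  } else { # missing_organ
    lung <- organOf("lung_l")
    region <- lung@values > 0
    v[region] <- case$spec$bodyHU
  }
  case$patient <- scalarVolume(v, grid)
  case$confounder <- list(kind = kind,
                          region = binaryMask(region, grid,
                                              paste0("confounder_", kind)))
  case
}
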
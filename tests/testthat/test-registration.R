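# Known-transform recovery on 64^3 CT-like phantoms.  The phantom cache is
# shared across the blocks; registrations run at the package defaults.

regCase <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePhantom(phantomSpec(
        seed = 3, nAtlases = 1, deformationMaxMm = 0,
        rotationRangeDeg = 0, translationRangeMm = 0,
        remapSlopeRange = c(1, 1), remapOffsetRange = c(0, 0)))
    cache
  }
})

test_that("a pure translation is recovered within half a voxel", {
  case <- regCase()
  g <- imageGrid(case$patient)
  base <- scalarVolume(voxelValues(case$base), g)
  # moving(x) = fixed(x + t): the true fixed-to-moving map is x - t
  tr <- c(12, -8, 5)
  moving <- resample(base, g, translationTransform(tr))
  aff <- suppressWarnings(registerAffine(case$patient, moving))
  expect_lt(max(abs(aff@translation + tr)), 0.5 * max(gridSpacing(g)))
  expect_lt(max(abs(aff@matrix - diag(3))), 0.03)
})

test_that("a 10 degree rotation about z is recovered within 1 degree", {
  case <- regCase()
  g <- imageGrid(case$patient)
  base <- scalarVolume(voxelValues(case$base), g)
  moving <- resample(base, g, rotationTransform(10, 3, gridCenter(g)))
  aff <- suppressWarnings(registerAffine(case$patient, moving))
  ang <- atan2(aff@matrix[2, 1], aff@matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-10)), 1)
  expect_lt(sqrt(sum(aff@translation^2)), 2)
})

test_that("self-registration stays near the identity", {
  case <- regCase()
  g <- imageGrid(case$patient)
  base <- scalarVolume(voxelValues(case$base), g)
  aff <- suppressWarnings(registerAffine(case$patient, base))
  expect_lt(max(abs(aff@matrix - diag(3))), 0.02)
  expect_lt(sqrt(sum(aff@translation^2)), 0.5 * max(gridSpacing(g)))
})

test_that("a known smooth deformation is recovered to under 2 mm in-mask
           and warped labels match the analytic warp", {
  case <- generatePhantom(phantomSpec(seed = 11, nAtlases = 1,
                                      deformationMaxMm = 8,
                                      rotationRangeDeg = 3,
                                      translationRangeMm = 5))
  g <- imageGrid(case$patient)
  a <- case$atlases[[1]]
  aff <- suppressWarnings(registerAffine(case$patient, a$volume))
  comp <- registerBspline(case$patient, a$volume, aff, a$masks)
  un <- Reduce(`|`, lapply(case$truth, function(m) voxelValues(m) > 0))
  pts <- indexToPhysical(g, which(un, arr.ind = TRUE) - 1)
  res <- sqrt(rowSums((transformPoints(comp, pts) -
                         transformPoints(a$transform, pts))^2))
  expect_lt(mean(res), 2)
  # warped masks against the analytically warped ground truth
  dsum <- vapply(names(case$truth), function(o)
    dice(resample(a$masks[[o]], g, comp), case$truth[[o]]), numeric(1))
  expect_gte(min(dsum[c("liver", "lung_l", "lung_r", "spleen")]), 0.9)
  expect_gte(mean(dsum), 0.85)
  # determinism: the full registration repeats bit-identically
  aff2 <- suppressWarnings(registerAffine(case$patient, a$volume))
  expect_identical(aff@matrix, aff2@matrix)
  expect_identical(aff@translation, aff2@translation)
})

test_that("zero-deformation initialisation stays under 1 mm of FFD motion", {
  case <- regCase()
  g <- imageGrid(case$patient)
  # moving is the affine-resampled fixed image itself, and the affine is
  # handed to the deformable stage: there is nothing left to recover
  aff <- rotationTransform(4, 3, gridCenter(g), translation = c(6, -4, 3))
  affInv <- affineTransform(solve(aff@matrix),
                            -as.numeric(solve(aff@matrix) %*%
                                          aff@translation),
                            aff@center)
  moving <- resample(case$patient, g, affInv)
  comp <- registerBspline(case$patient, moving, aff, case$truth["liver"])
  ffd <- comp@transforms[[2]]
  U <- ffdDisplacementField(ffd, g)
  inMask <- voxelValues(dilateMask(case$truth$liver, 10)) > 0
  disp <- sqrt(U[, , , 1]^2 + U[, , , 2]^2 + U[, , , 3]^2)
  expect_lt(max(disp[inMask]), 1)
})

test_that("mask-coverage failures raise a named error", {
  case <- regCase()
  g <- imageGrid(case$patient)
  base <- scalarVolume(voxelValues(case$base), g)
  # an affine throwing every sample far out of the mask region
  badAff <- translationTransform(c(5000, 0, 0))
  err <- tryCatch(
    registerBspline(case$patient, base, badAff, case$truth["spleen"]),
    error = identity)
  expect_s3_class(err, "atlasseg_mask_coverage")
  expect_match(conditionMessage(err), "spleen")
})
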
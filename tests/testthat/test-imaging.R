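test_that("grid geometry maps indices to physical points and back", {
  g <- volumeGrid(c(10, 12, 14), c(2.5, 1, 1.3), origin = c(5, -3, 2))
  idx <- rbind(c(0, 0, 0), c(9, 11, 13), c(3, 4, 5))
  p <- indexToPhysical(g, idx)
  expect_equal(p[1, ], c(5, -3, 2))
  expect_equal(physicalToIndex(g, p), idx, ignore_attr = TRUE)
  expect_error(volumeGrid(c(4, 4, 4), spacing = c(0, 1, 1)), "spacing")
  expect_error(volumeGrid(c(4, 4, 4), orientation = matrix(1, 3, 3)),
               "orthonormal")
})

test_that("resample is exact on the identity and on lattice-aligned shifts", {
  g <- volumeGrid(c(6, 6, 6), c(2, 2, 2))
  v <- scalarVolume(array(rnorm(216), c(6, 6, 6)), g)
  r <- resample(v, g, identityTransform())
  expect_equal(voxelValues(r), voxelValues(v))
  # one-voxel (2 mm) shift along axis 1: interior equals shifted input
  r2 <- resample(v, g, translationTransform(c(2, 0, 0)))
  expect_equal(voxelValues(r2)[1:5, , ], voxelValues(v)[2:6, , ])
  # half-voxel shift on a step volume: boundary is the arithmetic mean
  step <- array(0, c(6, 6, 6))
  step[4:6, , ] <- 10
  vs <- scalarVolume(step, g)
  r3 <- resample(vs, g, translationTransform(c(1, 0, 0)))
  expect_equal(voxelValues(r3)[3, 3, 3], 5)
  # masks stay binary under the mask method and preserve organ label
  m <- binaryMask(step > 0, g, "liver")
  rm <- resample(m, g, translationTransform(c(1, 0, 0)))
  expect_true(all(voxelValues(rm) %in% c(0, 1)))
  expect_identical(organLabel(rm), "liver")
})

test_that("out-of-field voxels take the declared fill values", {
  g <- volumeGrid(c(4, 4, 4))
  v <- scalarVolume(array(100, c(4, 4, 4)), g)
  r <- resample(v, g, translationTransform(c(10, 0, 0)))
  expect_true(all(voxelValues(r) == -1000))
  m <- binaryMask(array(1, c(4, 4, 4)), g)
  rm <- resample(m, g, translationTransform(c(10, 0, 0)))
  expect_true(all(voxelValues(rm) == 0))
})

test_that("dilation matches the brute-force Euclidean oracle", {
  # single voxel, isotropic 1 mm, 1 mm margin -> 7-voxel face-neighbour ball
  g <- volumeGrid(c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  d1 <- dilateMask(binaryMask(m, g), 1)
  expect_identical(maskVoxelCount(d1), 7L)
  # anisotropic: 2 mm margin on (2.5, 1, 1) spacing never crosses axis 1
  ga <- volumeGrid(c(5, 5, 5), c(2.5, 1, 1))
  d2 <- dilateMask(binaryMask(m, ga), 2)
  expect_true(all(which(voxelValues(d2) > 0, arr.ind = TRUE)[, 1] == 3))
  # margin 0 is the identity; empty mask warns and returns unchanged
  expect_identical(voxelValues(dilateMask(binaryMask(m, g), 0)),
                   voxelValues(binaryMask(m, g)))
  empty <- binaryMask(array(FALSE, c(5, 5, 5)), g)
  expect_warning(de <- dilateMask(empty, 3), "empty")
  expect_identical(maskVoxelCount(de), 0L)
  # random blobs vs oracle on anisotropic grids
  set.seed(7)
  for (rep in 1:3) {
    arr <- randomBlob(c(9, 8, 7))
    sp <- c(1.5, 1, 0.8)
    gb <- volumeGrid(c(9, 8, 7), sp)
    marg <- runif(1, 0.5, 3)
    got <- voxelValues(dilateMask(binaryMask(arr, gb), marg)) > 0
    want <- oracleEdtSq(arr, sp) <= marg^2 + 1e-9
    expect_identical(got, want)
  }
})

test_that("composed dilations stay within the single combined margin", {
  # triangle inequality on the voxel lattice: dilating by a then b can
  # never reach farther than dilating by a+b at once (the reverse
  # containment holds only in the continuum, not on a discrete grid)
  set.seed(3)
  arr <- randomBlob(c(10, 10, 10))
  g <- volumeGrid(c(10, 10, 10))
  m <- binaryMask(arr, g)
  ab <- dilateMask(dilateMask(m, 1.2), 0.9)
  whole <- dilateMask(m, 2.1)
  expect_true(all(voxelValues(whole) >= voxelValues(ab)))
  # and both contain the original
  expect_true(all(voxelValues(ab) >= voxelValues(m)))
})

test_that("signed distance matches the exact distance-transform oracle", {
  g <- volumeGrid(c(19, 19, 19), c(1.2, 1, 0.9))
  arr <- ballArray(c(19, 19, 19), c(10, 10, 10), 6)
  phi <- voxelValues(signedDistance(binaryMask(arr, g)))
  want <- oracleSignedDistance(arr, c(1.2, 1, 0.9))
  expect_equal(phi, want, tolerance = 1e-12, ignore_attr = TRUE)
  # centred ball: value at centre is about -radius (within one voxel)
  expect_lt(abs(phi[10, 10, 10] + 6), 1.3)
  # voxel just outside the boundary is positive and near the spacing scale
  expect_true(all(phi[!arr] > 0))
  # complement flips the sign near the interface
  phiC <- voxelValues(signedDistance(binaryMask(!arr, g)))
  nearIf <- abs(phi) < 2
  expect_lt(max(abs(phi[nearIf] + phiC[nearIf])), 1.5 * 1.2)
  expect_error(signedDistance(binaryMask(array(TRUE, c(3, 3, 3)),
                                         volumeGrid(c(3, 3, 3)))),
               "interface")
})

test_that("gradient magnitude is exact on ramps and scales linearly", {
  g <- volumeGrid(c(16, 8, 8), c(2, 1, 1))
  x <- array(rep((0:15) * 2 * 3, 64), c(16, 8, 8))   # f = 3 mm^-1 ramp
  v <- scalarVolume(x, g)
  gm <- voxelValues(gradientMagnitude(v, 0))
  expect_equal(max(abs(gm[2:15, , ] - 3)), 0, tolerance = 1e-10)
  # constant volume -> zero up to kernel round-off
  expect_lt(max(voxelValues(
    gradientMagnitude(scalarVolume(array(7, c(8, 8, 8))), 1))), 1e-10)
  # homogeneity for alpha > 0 at sigma 0
  set.seed(1)
  r <- scalarVolume(array(rnorm(512), c(8, 8, 8)))
  g1 <- voxelValues(gradientMagnitude(r, 0))
  g2 <- voxelValues(gradientMagnitude(scalarVolume(2.5 * voxelValues(r)), 0))
  expect_equal(g2, 2.5 * g1, tolerance = 1e-12)
})

test_that("smoothed 1D step edge peaks at the edge with the DoG response", {
  n <- 64
  g <- volumeGrid(c(n, 3, 3), c(1, 1, 1))
  stepv <- array(rep(c(rep(0, n / 2), rep(10, n / 2)), 9), c(n, 3, 3))
  gm <- voxelValues(gradientMagnitude(scalarVolume(stepv, g), 2))[, 2, 2]
  expect_true(which.max(gm) %in% c(n / 2, n / 2 + 1))
  # dense 1D convolution oracle: derivative-of-Gaussian response peak
  kern <- atlasseg:::gaussKernel1D(2, 1)
  sm <- stats::filter(c(rep(0, n / 2), rep(10, n / 2)), kern, sides = 2)
  dor <- (c(sm[-1], sm[n]) - c(sm[1], sm[-n])) / 2
  expect_equal(max(gm), max(dor, na.rm = TRUE), tolerance = 0.05)
})

test_that("largest connected component uses 26-connectivity", {
  g <- volumeGrid(c(8, 8, 8))
  arr <- array(FALSE, c(8, 8, 8))
  arr[1:3, 1:3, 1:3] <- TRUE        # 27 voxels
  arr[6, 6, 6] <- TRUE              # far crumb (not 26-adjacent)
  arr[4, 4, 4] <- TRUE              # diagonal-connected to the block
  keep <- largestComponent(binaryMask(arr, g))
  expect_identical(maskVoxelCount(keep), 28L)
  expect_true(voxelValues(keep)[4, 4, 4] == 1)
  expect_true(voxelValues(keep)[6, 6, 6] == 0)
})
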
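test_that("affine transforms compose about their centre", {
  tr <- affineTransform(diag(c(2, 1, 1)), c(3, 0, 0), center = c(10, 10, 10))
  p <- transformPoints(tr, rbind(c(10, 10, 10), c(11, 10, 10)))
  expect_equal(p[1, ], c(13, 10, 10))        # centre moves by t only
  expect_equal(p[2, ], c(15, 10, 10))        # doubled offset plus t
  rot <- rotationTransform(90, 3, center = c(0, 0, 0))
  expect_equal(transformPoints(rot, rbind(c(1, 0, 0))),
               rbind(c(0, 1, 0)), tolerance = 1e-12)
})

test_that("composite transforms apply right-to-left", {
  ffd <- ffdLattice(volumeGrid(c(8, 8, 8), c(10, 10, 10)), 30)
  ffd@coefficients[, , , 1] <- 5             # uniform +5 mm along x
  aff <- translationTransform(c(100, 0, 0))
  comp <- compositeTransform(aff, ffd)
  p <- transformPoints(comp, rbind(c(20, 20, 20)))
  expect_equal(p, rbind(c(125, 20, 20)), tolerance = 1e-9)
})

test_that("FFD evaluation is a partition-of-unity spline interpolation", {
  g <- volumeGrid(c(10, 10, 10), c(8, 8, 8))
  ffd <- ffdLattice(g, 25)
  # uniform coefficients reproduce the constant displacement everywhere
  ffd@coefficients[, , , 2] <- -3
  pts <- matrix(runif(60, 5, 60), ncol = 3)
  u <- ffdDisplacementAt(ffd, pts)
  expect_equal(u[, 2], rep(-3, 20), tolerance = 1e-12)
  expect_equal(u[, c(1, 3)], matrix(0, 20, 2), tolerance = 1e-12)
  # separable full-grid evaluation agrees with pointwise evaluation
  set.seed(6)
  ffd@coefficients <- array(rnorm(prod(ffd@nodeDim) * 3),
                            c(ffd@nodeDim, 3L))
  U <- ffdDisplacementField(ffd, g)
  gp <- gridPoints(g)
  Upt <- ffdDisplacementAt(ffd, gp)
  expect_equal(array(Upt, c(gridDim(g), 3L)), U, tolerance = 1e-10)
})

test_that("stage refinement reproduces the field at the new lattice nodes", {
  g <- volumeGrid(c(16, 16, 16), c(10, 10, 10))
  set.seed(13)
  coarse <- ffdLattice(g, 100)
  coarse@coefficients <- array(rnorm(prod(coarse@nodeDim) * 3, sd = 4),
                               c(coarse@nodeDim, 3L))
  fine <- ffdRefine(coarse, g, 40)
  nd <- fine@nodeDim
  # interior nodes only: the outermost shell lies outside the supported
  # domain, where evaluation clamps to the spline support
  nodes <- as.matrix(expand.grid(seq(1, nd[1] - 2), seq(1, nd[2] - 2),
                                 seq(1, nd[3] - 2)))
  pts <- sweep(sweep(nodes, 2, fine@nodeSpacing, "*"), 2,
               fine@nodeOrigin, "+")
  uOld <- ffdDisplacementAt(coarse, pts)
  uNew <- ffdDisplacementAt(fine, pts)
  expect_lt(max(abs(uOld - uNew)), 1e-6)
})

test_that("transforms serialize and reload losslessly", {
  dir <- withr::local_tempdir()
  aff <- affineTransform(matrix(c(1, .1, 0, -.1, 1, 0, 0, 0, 1.05), 3),
                         c(4, -2, 1), c(80, 80, 80))
  writeTransform(aff, file.path(dir, "aff"))
  aff2 <- readTransform(file.path(dir, "aff"))
  expect_equal(aff2@matrix, aff@matrix, tolerance = 1e-6)
  expect_equal(aff2@translation, aff@translation, tolerance = 1e-6)
  ffd <- ffdLattice(volumeGrid(c(8, 8, 8), c(10, 10, 10)), 40)
  set.seed(2)
  ffd@coefficients <- array(rnorm(prod(ffd@nodeDim) * 3),
                            c(ffd@nodeDim, 3L))
  comp <- compositeTransform(aff, ffd)
  writeTransform(comp, file.path(dir, "comp"))
  comp2 <- readTransform(file.path(dir, "comp"))
  pts <- matrix(runif(30, 10, 60), ncol = 3)
  expect_equal(transformPoints(comp2, pts), transformPoints(comp, pts),
               tolerance = 1e-5)
})

test_that("warpAtlasLabels preserves labels and lattice shifts exactly", {
  g <- volumeGrid(c(8, 8, 8), c(2, 2, 2))
  arr <- array(FALSE, c(8, 8, 8))
  arr[3:5, 3:5, 3:5] <- TRUE
  m <- binaryMask(arr, g, "kidney_l")
  out <- warpAtlasLabels(list(m), identityTransform(), g)
  expect_identical(voxelValues(out[[1]]), voxelValues(m))
  expect_identical(organLabel(out[[1]]), "kidney_l")
  shifted <- warpAtlasLabels(list(m), translationTransform(c(2, 0, 0)), g)
  expect_equal(sum(voxelValues(shifted[[1]])), sum(arr))
  expect_identical(voxelValues(shifted[[1]])[2:4, 3:5, 3:5],
                   voxelValues(m)[3:5, 3:5, 3:5])
})
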
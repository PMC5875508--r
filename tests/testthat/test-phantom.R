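test_that("phantom generation is seed-deterministic", {
  s <- phantomSpec(gridDim = 32, nAtlases = 2, seed = 4)
  a <- generatePhantom(s)
  b <- generatePhantom(s)
  expect_identical(voxelValues(a$patient), voxelValues(b$patient))
  expect_identical(voxelValues(a$atlases[[2]]$volume),
                   voxelValues(b$atlases[[2]]$volume))
  expect_identical(a$atlases[[1]]$transform@transforms[[2]]@coefficients,
                   b$atlases[[1]]$transform@transforms[[2]]@coefficients)
  c <- generatePhantom(phantomSpec(gridDim = 32, nAtlases = 2, seed = 5))
  expect_false(identical(voxelValues(a$patient), voxelValues(c$patient)))
})

test_that("atlas truth masks warped by the recorded transform match the
           patient truth", {
  case <- generatePhantom(phantomSpec(seed = 2))
  for (a in case$atlases) {
    for (o in names(case$truth)) {
      w <- resample(a$masks[[o]], imageGrid(case$patient), a$transform)
      expect_gte(dice(w, case$truth[[o]]), 0.99)
    }
  }
})

test_that("the degenerate phantom has atlases identical to the clean
           patient", {
  s <- phantomSpec(gridDim = 32, nAtlases = 2, seed = 1,
                   deformationMaxMm = 0, rotationRangeDeg = 0,
                   translationRangeMm = 0, remapSlopeRange = c(1, 1),
                   remapOffsetRange = c(0, 0), noiseSigmaHU = 0)
  case <- generatePhantom(s)
  expect_equal(voxelValues(case$atlases[[1]]$volume),
               voxelValues(case$patient), tolerance = 1e-9)
  for (o in names(case$truth))
    expect_identical(voxelValues(case$atlases[[1]]$masks[[o]]),
                     voxelValues(case$truth[[o]]))
})

test_that("organs are pairwise disjoint and deformation stays below the
           smallest organ radius", {
  case <- generatePhantom(phantomSpec(seed = 3))
  labs <- names(case$truth)
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    expect_identical(sum(voxelValues(case$truth[[labs[i]]]) *
                           voxelValues(case$truth[[labs[j]]])), 0)
  }
  expect_error(generatePhantom(phantomSpec(deformationMaxMm = 20)),
               "radius")
})

test_that("confounders modify the patient only and record their region", {
  case <- generatePhantom(phantomSpec(seed = 6))
  for (kind in c("artifact_blob", "blurred_pole", "attached_blob")) {
    mod <- addConfounder(case, kind)
    expect_identical(mod$confounder$kind, kind)
    reg <- voxelValues(mod$confounder$region) > 0
    expect_gt(sum(reg), 0)
    # patient altered inside (a neighbourhood of) the region, atlases not
    expect_false(identical(voxelValues(mod$patient),
                           voxelValues(case$patient)))
    expect_identical(voxelValues(mod$atlases[[1]]$volume),
                     voxelValues(case$atlases[[1]]$volume))
  }
  mo <- addConfounder(case, "missing_organ")
  lungRegion <- voxelValues(case$truth$lung_l) > 0
  expect_true(all(voxelValues(mo$patient)[lungRegion] >
                    voxelValues(case$patient)[lungRegion]))
  expect_error(addConfounder(case, "nope"))
})

test_that("phantom cases round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  case <- generatePhantom(phantomSpec(gridDim = 24, nAtlases = 2, seed = 9))
  writePhantom(case, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  p <- readVolume(file.path(dir, "patient.nii.gz"))
  expect_equal(voxelValues(p), voxelValues(case$patient),
               tolerance = 1e-5)
  expect_equal(gridSpacing(p), gridSpacing(case$patient), tolerance = 1e-5)
  m <- readMask(file.path(dir, "truth_liver.nii.gz"), "liver")
  expect_identical(voxelValues(m), voxelValues(case$truth$liver))
  tr <- readTransform(file.path(dir, "atlas1", "true_transform"))
  pts <- matrix(runif(30, 10, 50), ncol = 3)
  expect_equal(transformPoints(tr, pts),
               transformPoints(case$atlases[[1]]$transform, pts),
               tolerance = 1e-4)
})
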
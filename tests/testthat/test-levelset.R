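# Shared 64^3 CT-like test scene: a homogeneous 25 mm-radius organ (60 HU)
# in soft-tissue background (-100 HU), 2.5 mm voxels.
lsScene <- function(noise = 0) {
  g <- volumeGrid(c(64, 64, 64), c(2.5, 2.5, 2.5))
  ball <- atlasseg:::ellipsoidArray(g, gridCenter(g), c(25, 25, 25))
  vals <- array(-100, c(64, 64, 64)) + ball * 160
  if (noise > 0) {
    set.seed(42)
    vals <- vals + array(rnorm(64^3, sd = noise), c(64, 64, 64))
  }
  list(g = g, truth = binaryMask(ball, g, "ball"),
       vol = scalarVolume(vals, g))
}

test_that("threshold level set recovers a homogeneous ball from an eroded
           seed", {
  sc <- lsScene()
  seed <- erodeMask(sc$truth, 7.5)
  phi <- thresholdLevelSet(signedDistance(seed), sc$vol, c(40, 80))
  out <- levelSetToMask(phi, "ball")
  expect_gte(dice(out, sc$truth), 0.97)
  expect_lte(attr(phi, "iterations"), 500)
})

test_that("threshold level set eliminates out-of-interval leaks", {
  sc <- lsScene()
  blob <- atlasseg:::ellipsoidArray(sc$g, gridCenter(sc$g) + c(30, 0, 0),
                                    c(12, 12, 12))
  vol2 <- scalarVolume(voxelValues(sc$vol) + blob * 300, sc$g)  # 200 HU
  leakSeed <- binaryMask(voxelValues(sc$truth) > 0 | blob, sc$g, "ball")
  leakRegion <- blob & !(voxelValues(sc$truth) > 0)
  phi <- thresholdLevelSet(signedDistance(leakSeed), vol2, c(40, 80))
  remaining <- sum(voxelValues(levelSetToMask(phi))[leakRegion])
  expect_lte(remaining, 0.01 * sum(leakRegion))
  # >= 95% of the final foreground lies inside the HU interval (one bin
  # width of slack)
  out <- voxelValues(levelSetToMask(phi)) > 0
  hu <- voxelValues(vol2)[out]
  tol <- (80 - 40) / 125
  expect_gte(mean(hu >= 40 - tol & hu <= 80 + tol), 0.95)
})

test_that("zero speed with curvature only shrinks the volume", {
  sc <- lsScene()
  # empty interval: nothing in [-5000, -4000], so S = -1 everywhere; use
  # propagation 0 to isolate the curvature flow
  params <- levelSetParams(0, 0.5, maxIter = 60, rmsTol = 1e-9)
  phi <- thresholdLevelSet(signedDistance(sc$truth), sc$vol,
                           c(-5000, -4000), params = params)
  expect_lt(sum(voxelValues(phi) < 0), maskVoxelCount(sc$truth))
})

test_that("geodesic flow on a constant image is pure curvature shrinkage", {
  sc <- lsScene()
  const <- scalarVolume(array(0, c(64, 64, 64)), sc$g)
  startVol <- maskVoxelCount(sc$truth)
  phi <- geodesicLevelSet(signedDistance(sc$truth), const)
  expect_lt(sum(voxelValues(phi) < 0), startVol)
  expect_identical(attr(phi, "iterations"), 30L)
})

test_that("geodesic smoothing closes a notch carved into the organ border", {
  sc <- lsScene()
  notched <- voxelValues(sc$truth) > 0
  # notch carved into the +x face of the ball; its floor lies inside the
  # organ where the edge image is permissive, so the balloon and
  # curvature terms can close it while the surrounding true border
  # (strong gradient, g near 0) stays put
  face <- which(notched, arr.ind = TRUE)
  xmax <- max(face[, 1])
  notched[(xmax - 2):xmax, 30:35, 30:35] <- FALSE
  nm <- binaryMask(notched, sc$g, "ball")
  before <- dice(nm, sc$truth)
  phi <- geodesicLevelSet(signedDistance(nm), sc$vol)
  after <- dice(levelSetToMask(phi), sc$truth)
  expect_gt(after, before)
})

test_that("a single CFL-bounded step stays within the analytic update
           budget", {
  sc <- lsScene(noise = 8)
  seed <- erodeMask(sc$truth, 5)
  params <- levelSetParams(1, 0.5, maxIter = 1, rmsTol = 1e-12)
  init <- signedDistance(seed)
  phi <- thresholdLevelSet(init, sc$vol, c(40, 80), params = params)
  dt <- attr(phi, "dt")
  h <- gridSpacing(sc$vol)
  # discrete one-sided gradients of the (clamped) initial field bound the
  # one-step update: |dphi| <= dt (a |S| G + b |kappa|_cap G)
  cap <- 6 * max(h)
  p0 <- pmin(pmax(voxelValues(init), -cap), cap)
  G <- 0
  for (a in 1:3) {
    d <- abs(apply(p0, setdiff(1:3, 1), diff)) / h[a]
    p0 <- aperm(p0, c(2, 3, 1))
    G <- max(G, max(d))
  }
  G3 <- sqrt(3) * G
  bound <- dt * (1 * G3 + 0.5 * (1 / min(h)) * G3) + 1e-9
  # assert inside the narrow band only: outside it the comparison would
  # mix the clamp with the update
  band <- abs(voxelValues(init)) < cap
  delta <- abs(voxelValues(phi) - voxelValues(init))[band]
  expect_true(all(is.finite(voxelValues(phi))))
  expect_lt(max(delta), bound)
})

test_that("level-set steps are deterministic", {
  sc <- lsScene(noise = 8)
  seed <- erodeMask(sc$truth, 5)
  p <- levelSetParams(1, 0.5, maxIter = 80, rmsTol = 1e-9)
  a <- thresholdLevelSet(signedDistance(seed), sc$vol, c(40, 80), params = p)
  b <- thresholdLevelSet(signedDistance(seed), sc$vol, c(40, 80), params = p)
  expect_identical(voxelValues(a), voxelValues(b))
})

test_that("vanished interfaces raise a named error", {
  sc <- lsScene()
  tiny <- array(FALSE, c(64, 64, 64))
  tiny[32, 32, 32] <- TRUE
  init <- signedDistance(binaryMask(tiny, sc$g))
  err <- tryCatch(
    thresholdLevelSet(init, sc$vol, c(-5000, -4000),
                      params = levelSetParams(1, 0.5, maxIter = 200,
                                              rmsTol = 1e-12)),
    error = identity)
  expect_s3_class(err, "atlasseg_interface_vanished")
})
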
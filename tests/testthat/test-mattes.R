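miVol <- function(vals, g) scalarVolume(array(vals, gridDim(g)), g)

# Dense loop-based oracle of the same estimator: zero-order window on the
# fixed axis, cubic B-spline window on the moving axis, full sampling.
oracleMattes <- function(fv, mv, nb) {
  fr <- range(fv)
  fb <- pmin(floor((fv - fr[1]) / (diff(fr) / nb)), nb - 1)
  mr <- range(mv)
  mhat <- pmin(pmax((mv - mr[1]) / (diff(mr) / (nb - 4)) + 1.5, 1),
               nb - 2 - 1e-9)
  b3 <- function(t) {
    a <- abs(t)
    ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
           ifelse(a < 2, (2 - a)^3 / 6, 0))
  }
  P <- matrix(0, nb, nb)
  for (i in seq_along(fv)) {
    m0 <- floor(mhat[i]) - 1
    for (k in 0:3)
      P[fb[i] + 1, m0 + k + 1] <- P[fb[i] + 1, m0 + k + 1] +
        b3(mhat[i] - (m0 + k))
  }
  P <- P / length(fv)
  pf <- rowSums(P)
  pm <- colSums(P)
  sum(P[P > 0] * log(P[P > 0])) - sum(pf[pf > 0] * log(pf[pf > 0])) -
    sum(pm[pm > 0] * log(pm[pm > 0]))
}

test_that("the sampled metric equals a dense joint-histogram oracle and
           self-alignment is a local minimum", {
  set.seed(4)
  g <- volumeGrid(c(12, 12, 12))
  f <- miVol(rnorm(1728, 50, 20), g)
  m <- miVol(rnorm(1728, 30, 10) + 0.7 * voxelValues(f), g)
  cfg <- miMetricConfig(bins = 16, samplingFraction = 1)
  got <- mattesMI(f, m, identityTransform(), cfg)
  want <- -oracleMattes(as.numeric(voxelValues(f)),
                        as.numeric(voxelValues(m)), 16)
  expect_equal(got, want, tolerance = 1e-9)
  # small random perturbations never beat the identity alignment of an
  # image with itself
  g2 <- volumeGrid(c(20, 20, 20))
  f2 <- miVol(rnorm(8000, 50, 20), g2)
  cfg2 <- miMetricConfig(bins = 20, samplingFraction = 1)
  self <- mattesMI(f2, f2, identityTransform(), cfg2)
  for (i in 1:5) {
    tr <- translationTransform(runif(3, -2, 2))
    expect_gte(mattesMI(f2, f2, tr, cfg2), self)
  }
})

test_that("MI is stable under a monotone affine intensity remap", {
  set.seed(8)
  g <- volumeGrid(c(20, 20, 20))
  f <- miVol(rnorm(8000, 50, 20), g)
  cfg <- miMetricConfig(bins = 20, samplingFraction = 1)
  self <- mattesMI(f, f, identityTransform(), cfg)
  remap <- scalarVolume(2 * voxelValues(f) + 100, imageGrid(f))
  remapped <- mattesMI(f, remap, identityTransform(), cfg)
  expect_lt(abs(remapped - self), 0.05 * abs(self))
})

test_that("independent noise volumes carry (almost) no mutual information", {
  set.seed(12)
  g <- volumeGrid(c(24, 24, 24))
  f <- miVol(rnorm(24^3), g)
  m <- miVol(rnorm(24^3), g)
  negMI <- mattesMI(f, m, identityTransform(),
                    miMetricConfig(bins = 20, samplingFraction = 1))
  expect_lt(abs(negMI) / log(2), 0.05)   # < 0.05 bits
})

test_that("samples mapping outside the moving domain or mask are dropped", {
  set.seed(3)
  g <- volumeGrid(c(12, 12, 12))
  f <- miVol(rnorm(1728), g)
  # a transform pushing everything far outside leaves too few samples
  err <- tryCatch(
    mattesMI(f, f, translationTransform(c(500, 0, 0)),
             miMetricConfig(bins = 20, samplingFraction = 1)),
    error = identity)
  expect_s3_class(err, "atlasseg_metric_degenerate")
  # a moving mask restricts the usable samples the same way
  tiny <- array(FALSE, c(12, 12, 12))
  tiny[1:2, 1:2, 1:2] <- TRUE
  err2 <- tryCatch(
    mattesMI(f, f, identityTransform(),
             miMetricConfig(bins = 20, samplingFraction = 1),
             movingMask = binaryMask(tiny, g)),
    error = identity)
  expect_s3_class(err2, "atlasseg_metric_degenerate")
})

test_that("metric sampling is deterministic for a fixed seed", {
  set.seed(99)
  g <- volumeGrid(c(16, 16, 16))
  f <- miVol(rnorm(4096), g)
  m <- miVol(rnorm(4096, 10, 4), g)
  cfg <- miMetricConfig(bins = 16, samplingFraction = 0.5, seed = 7)
  v1 <- mattesMI(f, m, identityTransform(), cfg)
  v2 <- mattesMI(f, m, identityTransform(), cfg)
  expect_identical(v1, v2)
  cfg2 <- miMetricConfig(bins = 16, samplingFraction = 0.5, seed = 8)
  expect_false(identical(v1, mattesMI(f, m, identityTransform(), cfg2)))
})
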
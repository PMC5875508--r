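toyMasks <- function(arrs, g) lapply(arrs, binaryMask, grid = g)

test_that("perfect agreement drives w to the common mask and p,q to 1", {
  g <- volumeGrid(c(5, 5, 3))
  a <- array(0, c(5, 5, 3))
  a[2:4, 2:4, 2] <- 1
  st <- staple(toyMasks(list(a, a, a), g))
  expect_lt(max(abs(voxelValues(st$map) - a)), 1e-5)
  expect_true(all(st$performance$p > 0.999))
  expect_true(all(st$performance$q > 0.999))
})

test_that("staple matches the independent EM oracle on random rater sets", {
  set.seed(21)
  for (rep in 1:10) {
    d <- c(6, 6, 3)
    g <- volumeGrid(d)
    N <- sample(3:5, 1)
    arrs <- replicate(N, array(runif(prod(d)) < 0.4, d), simplify = FALSE)
    if (all(!vapply(arrs, any, logical(1)))) arrs[[1]][3, 3, 2] <- TRUE
    st <- staple(toyMasks(arrs, g), restrict = FALSE)
    D <- vapply(arrs, as.numeric, numeric(prod(d)))
    want <- oracleStaple(D, prior = mean(colMeans(D)))
    expect_equal(as.numeric(voxelValues(st$map)), want$w, tolerance = 1e-9)
    expect_equal(st$performance$p, want$p, tolerance = 1e-9)
    expect_equal(st$performance$q, want$q, tolerance = 1e-9)
  }
})

test_that("complete disagreement reaches the prior-driven fixed point", {
  d <- c(4, 4, 2)
  g <- volumeGrid(d)
  a <- array(0, d)
  a[1:2, , ] <- 1
  b <- 1 - a
  st <- staple(toyMasks(list(a, b), g), restrict = FALSE)
  w <- as.numeric(voxelValues(st$map))
  expect_true(all(is.finite(w)))
  D <- cbind(as.numeric(a), as.numeric(b))
  want <- oracleStaple(D, prior = mean(colMeans(D)))
  expect_equal(w, want$w, tolerance = 1e-9)
})

test_that("staple is invariant to rater ordering", {
  set.seed(5)
  d <- c(6, 5, 3)
  g <- volumeGrid(d)
  arrs <- replicate(3, array(runif(prod(d)) < 0.35, d), simplify = FALSE)
  s1 <- staple(toyMasks(arrs, g))
  s2 <- staple(toyMasks(arrs[c(3, 1, 2)], g))
  expect_equal(voxelValues(s1$map), voxelValues(s2$map), tolerance = 1e-12)
  expect_equal(sort(s1$performance$p), sort(s2$performance$p),
               tolerance = 1e-12)
})

test_that("duplicating a rater never lowers w on that rater's foreground", {
  set.seed(9)
  d <- c(6, 6, 3)
  g <- volumeGrid(d)
  arrs <- replicate(3, array(runif(prod(d)) < 0.4, d), simplify = FALSE)
  base <- staple(toyMasks(arrs, g), restrict = FALSE)
  dup <- staple(toyMasks(c(arrs, arrs[3]), g), restrict = FALSE)
  fg <- arrs[[3]]
  expect_true(all(voxelValues(dup$map)[fg] >=
                    voxelValues(base$map)[fg] - 1e-9))
})

test_that("degenerate rater sets are rejected", {
  g <- volumeGrid(c(4, 4, 2))
  empty <- array(0, c(4, 4, 2))
  full <- array(1, c(4, 4, 2))
  expect_error(staple(toyMasks(list(empty, empty), g)), "empty")
  expect_error(staple(toyMasks(list(full, full), g)), "background")
  expect_error(staple(toyMasks(list(full), g)))
})

test_that("probability thresholding is inclusive and keeps one component", {
  d <- c(10, 6, 3)
  g <- volumeGrid(d)
  w <- array(0, d)
  w[2, 2, 2] <- 0.69
  w[3, 2, 2] <- 0.70
  w[4, 2, 2] <- 0.71
  # attach more voxels so the >= 0.70 block is the largest component
  w[3:4, 3:4, 2] <- 0.9
  pm <- new("ProbabilityMap", grid = g, w = w, prior = 0.5,
            iterationsRun = 1L)
  m <- thresholdProbability(pm, 0.7, organLabel = "liver")
  expect_identical(voxelValues(m)[2, 2, 2], 0)   # 0.69 excluded
  expect_identical(voxelValues(m)[3, 2, 2], 1)   # 0.70 kept (inclusive)
  # two components: only the larger survives
  w2 <- array(0, d)
  w2[1:5, 1:5, 1:2] <- 0.9          # 50 voxels
  w2[9:10, 5:6, 3] <- 0.9           # 4-voxel crumb
  pm2 <- new("ProbabilityMap", grid = g, w = w2, prior = 0.5,
             iterationsRun = 1L)
  m2 <- thresholdProbability(pm2, 0.7)
  expect_identical(maskVoxelCount(m2), 50L)
  # empty result names the organ in a fusion-failure error
  pm3 <- new("ProbabilityMap", grid = g, w = array(0.1, d), prior = 0.5,
             iterationsRun = 1L)
  err <- tryCatch(thresholdProbability(pm3, 0.7, organLabel = "spleen"),
                  error = identity)
  expect_s3_class(err, "atlasseg_fusion_failure")
  expect_match(conditionMessage(err), "spleen")
})
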
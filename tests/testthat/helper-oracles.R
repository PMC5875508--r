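# Independent oracles used across the suite.  These are deliberately
# simple, loop-based implementations kept apart from the package's code
# paths.

# Brute-force squared Euclidean distance transform (all-pairs).
oracleEdtSq <- function(feature, spacing) {
  d <- dim(feature)
  pts <- which(feature, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- ((i - pts[, 1]) * spacing[1])^2 +
      ((j - pts[, 2]) * spacing[2])^2 +
      ((k - pts[, 3]) * spacing[3])^2
    out[i, j, k] <- min(dd)
  }
  out
}

# Brute-force signed distance (voxel-centre convention, negative inside).
oracleSignedDistance <- function(maskArr, spacing) {
  dOut <- sqrt(oracleEdtSq(maskArr, spacing))
  dIn <- sqrt(oracleEdtSq(!maskArr, spacing))
  phi <- dOut
  phi[maskArr] <- -dIn[maskArr]
  phi
}

# Straightforwardly coded STAPLE EM, same initialisation and iteration
# structure as specified: E-step then M-step, stop on max |delta w| < tol.
oracleStaple <- function(D, prior, maxIter = 20, tol = 1e-6,
                         initP = 0.9, initQ = 0.9) {
  n <- nrow(D)
  N <- ncol(D)
  p <- rep(initP, N)
  q <- rep(initQ, N)
  w <- NULL
  for (it in seq_len(maxIter)) {
    wNew <- numeric(n)
    for (i in seq_len(n)) {
      a <- prior
      b <- 1 - prior
      for (j in seq_len(N)) {
        if (D[i, j] == 1) {
          a <- a * p[j]
          b <- b * (1 - q[j])
        } else {
          a <- a * (1 - p[j])
          b <- b * q[j]
        }
      }
      wNew[i] <- a / (a + b)
    }
    if (!is.null(w) && max(abs(wNew - w)) < tol) {
      w <- wNew
      break
    }
    w <- wNew
    for (j in seq_len(N)) {
      p[j] <- min(max(sum(w * D[, j]) / sum(w), 1e-6), 1 - 1e-6)
      q[j] <- min(max(sum((1 - w) * (1 - D[, j])) / sum(1 - w), 1e-6),
                  1 - 1e-6)
    }
  }
  list(w = w, p = p, q = q)
}

# Exhaustive multi-level Otsu: search every placement of (classes-1) cuts.
oracleOtsuCuts <- function(counts, centers, classes) {
  nb <- length(counts)
  cw <- cumsum(c(0, counts))
  cs <- cumsum(c(0, counts * centers))
  seg <- function(a, b) {
    w <- cw[b + 1] - cw[a]
    s <- cs[b + 1] - cs[a]
    if (w > 0) s^2 / w else 0
  }
  combs <- utils::combn(nb - 1, classes - 1)
  bestScore <- -Inf
  bestCuts <- NULL
  for (c in seq_len(ncol(combs))) {
    cuts <- combs[, c]
    b <- c(0, cuts, nb)
    sc <- 0
    for (s in seq_len(classes)) sc <- sc + seg(b[s] + 1, b[s + 1])
    if (sc > bestScore) {
      bestScore <- sc
      bestCuts <- cuts
    }
  }
  list(cuts = bestCuts, score = bestScore)
}

# All-pairs surface distances between two boundary voxel sets.
oracleSurfaceStats <- function(aArr, bArr, spacing) {
  boundary <- function(v) {
    d <- dim(v)
    out <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        if (!v[i, j, k]) next
        nb <- c(
          if (i > 1) v[i - 1, j, k] else FALSE,
          if (i < d[1]) v[i + 1, j, k] else FALSE,
          if (j > 1) v[i, j - 1, k] else FALSE,
          if (j < d[2]) v[i, j + 1, k] else FALSE,
          if (k > 1) v[i, j, k - 1] else FALSE,
          if (k < d[3]) v[i, j, k + 1] else FALSE)
        if (!all(nb)) out[i, j, k] <- TRUE
      }
    out
  }
  pa <- sweep(which(boundary(aArr), arr.ind = TRUE), 2, spacing, "*")
  pb <- sweep(which(boundary(bArr), arr.ind = TRUE), 2, spacing, "*")
  sq <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  dm <- sqrt(pmax(sq, 0))
  aToB <- apply(dm, 1, min)
  bToA <- apply(dm, 2, min)
  list(msd = (mean(aToB) + mean(bToA)) / 2,
       hausdorff = max(max(aToB), max(bToA)))
}

# Random blob mask: union of a few random balls, guaranteed nonempty.
randomBlob <- function(d, spacing = c(1, 1, 1), nBalls = 3) {
  arr <- array(FALSE, d)
  for (b in seq_len(nBalls)) {
    ctr <- runif(3, 2, d - 1)
    r <- runif(1, 1.5, min(d) / 3)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        if (sum(((c(i, j, k) - ctr))^2) <= r^2) arr[i, j, k] <- TRUE
  }
  if (!any(arr)) arr[ceiling(d[1] / 2), ceiling(d[2] / 2),
                     ceiling(d[3] / 2)] <- TRUE
  arr
}

ballArray <- function(d, center, radiusVox) {
  arr <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (sum((c(i, j, k) - center)^2) <= radiusVox^2) arr[i, j, k] <- TRUE
  arr
}
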
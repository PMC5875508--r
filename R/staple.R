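# STAPLE: Simultaneous Truth and Performance Level Estimation.  Classic
# binary EM over N rater (warped-atlas) masks: the E-step computes the
# voxelwise posterior that the latent true segmentation is foreground, the
# M-step re-estimates each rater's sensitivity p and specificity q.

#' STAPLE fusion of warped atlas masks
#'
#' E-step: \eqn{w_i = a_i/(a_i+b_i)} with
#' \eqn{a_i = \pi \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}} and
#' \eqn{b_i = (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}};
#' M-step: \eqn{p_j = \sum_i w_i D_{ij} / \sum_i w_i},
#' \eqn{q_j = \sum_i (1-w_i)(1-D_{ij}) / \sum_i (1-w_i)}.
#' The global prior \eqn{\pi} is the mean rater foreground fraction over
#' the computation region (the bounding box of the union of masks dilated
#' by one voxel; \eqn{w = 0} outside).  Runs \code{maxIter} iterations or
#' until the largest change in \eqn{w} falls below \code{tol}.
#'
#' @param masks list of N >= 2 \linkS4class{BinaryMask}s on one grid
#' @param maxIter EM iteration cap (default 20)
#' @param tol convergence threshold on max |delta w| (default 1e-6)
#' @param initP,initQ initial sensitivity/specificity per rater
#' @param restrict compute over the dilated union bounding box only
#'   (default TRUE); the prior is region-sensitive, so this is configurable
#' @return list with \code{map} (a \linkS4class{ProbabilityMap}) and
#'   \code{performance} (data.frame of per-rater p and q)
#' @export
staple <- function(masks, maxIter = 20, tol = 1e-6,
                   initP = 0.9, initQ = 0.9, restrict = TRUE) {
  stopifnot(length(masks) >= 2)
  for (m in masks[-1]) stopifnotSameGrid(masks[[1]], m)
  grid <- masks[[1]]@grid
  d <- grid@dim
  D <- vapply(masks, function(m) as.numeric(m@values), numeric(prod(d)))
  if (all(colSums(D) == 0)) stop("all rater masks are empty", call. = FALSE)
  if (all(colSums(1 - D) == 0))
    stop("all rater masks are full: no background evidence", call. = FALSE)

  sel <- seq_len(prod(d))
  if (restrict) {
    u <- array(rowSums(D) > 0, d)
    ijk <- which(u, arr.ind = TRUE)
    lo <- pmax(apply(ijk, 2, min) - 1L, 1L)
    hi <- pmin(apply(ijk, 2, max) + 1L, d)
    inBox <- array(FALSE, d)
    inBox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    sel <- which(inBox)
    D <- D[sel, , drop = FALSE]
  }
  N <- ncol(D)
  prior <- mean(colMeans(D))
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  p <- rep(clamp(initP), N)
  q <- rep(clamp(initQ), N)
  w <- NULL
  iters <- 0L
  for (it in seq_len(maxIter)) {
    a <- rep(prior, nrow(D))
    b <- rep(1 - prior, nrow(D))
    for (j in seq_len(N)) {
      a <- a * ifelse(D[, j] == 1, p[j], 1 - p[j])
      b <- b * ifelse(D[, j] == 1, 1 - q[j], q[j])
    }
    wNew <- a / (a + b)
    iters <- it
    if (!is.null(w) && max(abs(wNew - w)) < tol) {
      w <- wNew
      break
    }
    w <- wNew
    sw <- sum(w)
    sb <- sum(1 - w)
    p <- clamp(colSums(w * D) / max(sw, .Machine$double.eps))
    q <- clamp(colSums((1 - w) * (1 - D)) / max(sb, .Machine$double.eps))
  }
  wFull <- array(0, d)
  wFull[sel] <- w
  map <- new("ProbabilityMap", grid = grid, w = wFull, prior = prior,
             iterationsRun = iters)
  list(map = map,
       performance = data.frame(rater = seq_len(N), p = p, q = q))
}

#' Threshold a STAPLE probability map into the refinement seed
#'
#' Foreground where \eqn{w \ge} \code{threshold} (inclusive); by default
#' only the largest 26-connected component is kept so that disconnected
#' crumbs cannot seed the level-set refinement.
#'
#' @param map a \linkS4class{ProbabilityMap}
#' @param threshold probability cut in (0, 1); default 0.7
#' @param organLabel organ name for the output mask (and error messages)
#' @param keepLargest retain only the largest connected component
#' @return a \linkS4class{BinaryMask}
#' @export
thresholdProbability <- function(map, threshold = 0.7,
                                 organLabel = "organ", keepLargest = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  m <- binaryMask(map@w >= threshold, map@grid, organLabel)
  if (sum(m@values) == 0)
    stop(errorCondition(
      sprintf("fusion failure for organ '%s': no voxel reaches w >= %.2f%s",
              organLabel, threshold, "; needs manual segmentation"),
      class = "atlasseg_fusion_failure"))
  if (keepLargest) m <- largestComponent(m)
  m
}
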
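# Multi-level Otsu extraction of the organ Hounsfield-unit interval: the
# in-mask histogram is split into k classes by maximising the between-class
# variance, and the largest class is taken to be the tissue sought; its
# min/max original HU become the threshold level-set interval.

#' HUInterval: automatically extracted organ intensity range
#'
#' @slot lower,upper HU bounds (lower <= upper)
#' @slot thresholds HU values of the class cuts
#' @slot classHistogram per-bin voxel counts of the in-mask histogram
#' @slot classOfVoxel class id (1..classes) per in-mask voxel
#' @slot largestClass id of the class chosen as the organ tissue
#' @slot fallback TRUE when the histogram was degenerate and the interval
#'   fell back to the raw in-mask range
#' @export
setClass("HUInterval",
  representation(lower = "numeric", upper = "numeric",
                 thresholds = "numeric", classHistogram = "numeric",
                 classOfVoxel = "integer", largestClass = "integer",
                 fallback = "logical"),
  validity = function(object) {
    if (object@lower > object@upper) return("lower must be <= upper")
    TRUE
  })

setMethod("show", "HUInterval", function(object) {
  cat(sprintf("HUInterval [%.1f, %.1f] HU (class %d of %d%s)\n",
              object@lower, object@upper, object@largestClass,
              length(object@thresholds) + 1L,
              if (object@fallback) ", fallback" else ""))
})

# Between-class variance of a histogram split at the given cut positions
# (cuts are the last bin index of each class but the final one).
betweenClassVariance <- function(counts, centers, cuts) {
  b <- c(0, cuts, length(counts))
  w <- diff(cumsum(c(0, counts))[b + 1])
  s <- diff(cumsum(c(0, counts * centers))[b + 1])
  ok <- w > 0
  sum(s[ok]^2 / w[ok])   # sum w_c mu_c^2 (global-mean term is constant)
}

# Dynamic-programming maximisation of the between-class variance over all
# placements of (classes - 1) cuts in `bins` bins.
otsuMultiThreshold <- function(counts, centers, classes) {
  nb <- length(counts)
  cw <- cumsum(c(0, counts))
  cs <- cumsum(c(0, counts * centers))
  # segScore[a, b]: w * mu^2 of bins a..b (1-based, inclusive)
  segScore <- function(a, b) {
    w <- cw[b + 1] - cw[a]
    s <- cs[b + 1] - cs[a]
    ifelse(w > 0, s^2 / w, 0)
  }
  # best[c, b] = max score of splitting bins 1..b into c classes
  best <- matrix(-Inf, classes, nb)
  argc <- array(0L, c(classes, nb))
  best[1, ] <- segScore(1, seq_len(nb))
  for (cc in 2:classes) {
    for (b in cc:nb) {
      prev <- (cc - 1):(b - 1)
      sc <- best[cc - 1, prev] + segScore(prev + 1, b)
      k <- which.max(sc)
      best[cc, b] <- sc[k]
      argc[cc, b] <- prev[k]
    }
  }
  cuts <- integer(classes - 1)
  b <- nb
  for (cc in classes:2) {
    cuts[cc - 1] <- argc[cc, b]
    b <- argc[cc, b]
  }
  list(cuts = cuts, score = best[classes, nb])
}

#' Extract the organ HU interval by multi-level Otsu analysis
#'
#' Builds a histogram of the in-mask HU values (default 125 equal-width
#' bins over the in-mask range, right-inclusive last bin), finds the
#' \code{classes - 1} thresholds maximising the between-class variance,
#' identifies the class holding the most voxels (ties broken toward the
#' class containing the in-mask median HU), and returns the minimum and
#' maximum original HU value among that class's voxels.
#'
#' @param volume the CT \linkS4class{ScalarVolume}
#' @param mask the organ-approximation \linkS4class{BinaryMask}
#' @param bins histogram bins (default 125)
#' @param classes number of classes (default 4)
#' @return an \linkS4class{HUInterval}
#' @export
otsuHuInterval <- function(volume, mask, bins = 125, classes = 4) {
  stopifnotSameGrid(volume, mask)
  vals <- volume@values[mask@values > 0]
  if (length(vals) < 2 * classes || length(unique(vals)) < classes)
    stop(errorCondition(
      sprintf("degenerate histogram: %d voxels, %d distinct values (< %d classes)",
              length(vals), length(unique(vals)), classes),
      class = "atlasseg_degenerate_histogram"))
  r <- range(vals)
  width <- diff(r) / bins
  binOf <- pmin(pmax(floor((vals - r[1]) / width) + 1L, 1L), bins)
  counts <- tabulate(binOf, bins)
  centers <- r[1] + (seq_len(bins) - 0.5) * width
  fit <- otsuMultiThreshold(counts, centers, classes)
  classOfBin <- findInterval(seq_len(bins), fit$cuts + 1L) + 1L
  classOf <- classOfBin[binOf]
  sizes <- tabulate(classOf, classes)
  top <- which(sizes == max(sizes))
  if (length(top) > 1L) {
    medianClass <- classOf[which.min(abs(vals - median(vals)))]
    top <- if (medianClass %in% top) medianClass else top[1]
  }
  inTop <- classOf == top
  new("HUInterval", lower = min(vals[inTop]), upper = max(vals[inTop]),
      thresholds = r[1] + fit$cuts * width, classHistogram = as.numeric(counts),
      classOfVoxel = as.integer(classOf), largestClass = as.integer(top),
      fallback = FALSE)
}
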
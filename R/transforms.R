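#' SpatialTransform: virtual parent of all spatial maps
#'
#' Transforms follow the resampling convention: they map fixed-image
#' (patient) physical points into moving-image (atlas) physical space, so a
#' warped atlas can be evaluated on the patient grid.
#' @export
setClass("SpatialTransform", representation("VIRTUAL"))

#' IdentityTransform
#' @export
setClass("IdentityTransform", contains = "SpatialTransform")

#' @describeIn IdentityTransform-class constructor
#' @return an \linkS4class{IdentityTransform}
#' @export
identityTransform <- function() new("IdentityTransform")

#' AffineTransform: rotation/scale/shear about a centre plus translation
#'
#' Maps a point x to \code{matrix \%*\% (x - center) + center + translation}.
#'
#' @slot matrix invertible 3 x 3 matrix
#' @slot translation mm triple
#' @slot center mm triple, centre of rotation/scaling
#' @export
setClass("AffineTransform", contains = "SpatialTransform",
  representation(matrix = "matrix", translation = "numeric",
                 center = "numeric"),
  validity = function(object) {
    if (!all(dim(object@matrix) == c(3L, 3L)))
      return("matrix must be 3x3")
    if (abs(det(object@matrix)) <= 1e-10)
      return("matrix must be invertible")
    if (length(object@translation) != 3L || length(object@center) != 3L)
      return("translation and center must be mm triples")
    TRUE
  })

#' Construct an AffineTransform
#' @param matrix 3 x 3 linear part (default identity)
#' @param translation mm triple (default zero)
#' @param center rotation/scale centre, mm triple (default origin)
#' @return an \linkS4class{AffineTransform}
#' @export
affineTransform <- function(matrix = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  new("AffineTransform", matrix = matrix,
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Pure translation transform
#' @param translation mm triple
#' @return an \linkS4class{AffineTransform} with identity linear part
#' @export
translationTransform <- function(translation)
  affineTransform(translation = translation)

#' Rigid rotation about an axis through a centre
#' @param angleDeg rotation angle, degrees
#' @param axis 1, 2 or 3: grid axis to rotate about
#' @param center mm triple
#' @param translation optional additional mm translation
#' @return an \linkS4class{AffineTransform}
#' @export
rotationTransform <- function(angleDeg, axis = 3, center = c(0, 0, 0),
                              translation = c(0, 0, 0)) {
  a <- angleDeg * pi / 180
  R2 <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  M <- diag(3)
  ij <- setdiff(1:3, axis)
  M[ij, ij] <- R2
  affineTransform(M, translation, center)
}

#' BSplineFFD: cubic B-spline free-form deformation
#'
#' A displacement field parameterised by mm displacement vectors on a
#' regular, axis-aligned control-node lattice covering the fixed-image
#' domain plus the cubic-spline support pad.  The displacement at any point
#' is the tensor-product cubic B-spline interpolation of the node
#' coefficients; the transform maps x to x + u(x).
#'
#' @slot nodeOrigin mm triple, physical position of node (0,0,0)
#' @slot nodeSpacing mm triple between nodes
#' @slot nodeDim integer triple of nodes per axis
#' @slot coefficients 4D array (nodeDim x 3) of mm displacements
#' @export
setClass("BSplineFFD", contains = "SpatialTransform",
  representation(nodeOrigin = "numeric", nodeSpacing = "numeric",
                 nodeDim = "integer", coefficients = "array"),
  validity = function(object) {
    if (!identical(dim(object@coefficients),
                   c(as.integer(object@nodeDim), 3L)))
      return("coefficients must have dim c(nodeDim, 3)")
    if (any(object@nodeSpacing <= 0))
      return("nodeSpacing must be > 0")
    if (any(object@nodeDim < 4L))
      return("need at least 4 nodes per axis for cubic interpolation")
    TRUE
  })

#' CompositeTransform: ordered transform chain
#'
#' The transform list is applied right-to-left on fixed-space points, so
#' \code{list(affine, ffd)} maps x to \code{affine(x + u(x))}: the B-spline
#' deformation acts in patient space and the affine carries the result into
#' atlas space.
#'
#' @slot transforms list of \linkS4class{SpatialTransform}s
#' @export
setClass("CompositeTransform", contains = "SpatialTransform",
  representation(transforms = "list"),
  validity = function(object) {
    ok <- vapply(object@transforms, function(t) is(t, "SpatialTransform"),
                 logical(1))
    if (!all(ok)) return("all elements must be SpatialTransforms")
    TRUE
  })

#' Construct a CompositeTransform
#' @param ... transforms, outermost first (applied right-to-left)
#' @return a \linkS4class{CompositeTransform}
#' @export
compositeTransform <- function(...) {
  new("CompositeTransform", transforms = list(...))
}

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "IdentityTransform",
          function(transform, points) points)

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "AffineTransform", function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  ctr <- rep(1, nrow(points)) %o% transform@center
  (points - ctr) %*% t(transform@matrix) + ctr +
    rep(1, nrow(points)) %o% transform@translation
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "BSplineFFD", function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  points + ffdDisplacementAt(transform, points)
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "CompositeTransform",
          function(transform, points) {
  for (tr in rev(transform@transforms)) points <- transformPoints(tr, points)
  points
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform\n  matrix:\n")
  print(signif(object@matrix, 4))
  cat("  translation:", paste(signif(object@translation, 4), collapse = ", "),
      "mm; center:", paste(signif(object@center, 4), collapse = ", "), "mm\n")
})

setMethod("show", "BSplineFFD", function(object) {
  cat("BSplineFFD:", paste(object@nodeDim, collapse = " x "),
      "nodes, spacing", paste(signif(object@nodeSpacing, 4), collapse = "/"),
      sprintf("mm, max |displacement| %.3f mm\n",
              max(abs(object@coefficients))))
})

setMethod("show", "CompositeTransform", function(object) {
  cat("CompositeTransform of", length(object@transforms),
      "transforms (applied right-to-left):\n")
  for (tr in object@transforms) show(tr)
})

# ---- cubic B-spline kernel -------------------------------------------------

bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

bspline3Deriv <- function(t) {
  a <- abs(t)
  v <- ifelse(a < 1, -2 * a + 1.5 * a^2,
              ifelse(a < 2, -(2 - a)^2 / 2, 0))
  v * sign(t)
}

# ---- FFD lattice helpers ---------------------------------------------------

# Physical axis-aligned bounding box of a grid's voxel centres
gridBBox <- function(grid) {
  d <- grid@dim
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  p <- indexToPhysical(grid, corners)
  rbind(lo = apply(p, 2, min), hi = apply(p, 2, max))
}

#' Create a zero-displacement B-spline lattice covering a grid
#'
#' The lattice extends one node spacing beyond the image bounding box on the
#' low side and enough nodes on the high side that every point of the domain
#' has full cubic support.
#'
#' @param grid the fixed-image \linkS4class{VolumeGrid}
#' @param nodeSpacingMm control-node spacing in mm (scalar or triple)
#' @return a \linkS4class{BSplineFFD} with zero coefficients
#' @export
ffdLattice <- function(grid, nodeSpacingMm) {
  if (length(nodeSpacingMm) == 1L) nodeSpacingMm <- rep(nodeSpacingMm, 3L)
  bb <- gridBBox(grid)
  extent <- bb["hi", ] - bb["lo", ]
  nd <- as.integer(floor(extent / nodeSpacingMm) + 4)
  new("BSplineFFD", nodeOrigin = as.numeric(bb["lo", ] - nodeSpacingMm),
      nodeSpacing = as.numeric(nodeSpacingMm), nodeDim = nd,
      coefficients = array(0, c(nd, 3L)))
}

# Continuous lattice coordinates of physical points, clamped to the valid
# support range [1, n-2] so evaluation degrades gracefully at the pad edge.
ffdLatticeCoords <- function(ffd, points) {
  u <- sweep(sweep(points, 2L, ffd@nodeOrigin, "-"), 2L,
             ffd@nodeSpacing, "/")
  for (a in 1:3) {
    u[, a] <- pmin(pmax(u[, a], 1), ffd@nodeDim[a] - 2 - 1e-9)
  }
  u
}

#' Sparse cubic B-spline weight matrix for a fixed point set
#'
#' Row i holds the 64 tensor-product basis weights of point i over the
#' control nodes; \code{W \%*\% matrix(coefficients, ncol = 3)} evaluates the
#' displacement at every point, and \code{t(W)} projects pointwise metric
#' gradients back onto the nodes.  The matrix depends only on the (fixed)
#' point positions, so it is built once per registration stage.
#'
#' @param ffd a \linkS4class{BSplineFFD} (lattice geometry only is used)
#' @param points n x 3 matrix of fixed-space physical points (mm)
#' @return a \code{dgCMatrix} of dim n x prod(nodeDim)
#' @export
ffdWeightMatrix <- function(ffd, points) {
  u <- ffdLatticeCoords(ffd, matrix(as.numeric(points), ncol = 3L))
  n <- nrow(u)
  i0 <- floor(u) - 1          # first support node per axis (0-based)
  f <- u - (i0 + 1)           # fractional position relative to node i0+1
  nd <- ffd@nodeDim
  wts <- list()
  for (a in 1:3) {
    w <- matrix(0, n, 4L)
    for (k in 0:3) w[, k + 1] <- bspline3(u[, a] - (i0[, a] + k))
    wts[[a]] <- w
  }
  nent <- n * 64L
  ii <- integer(nent); jj <- integer(nent); xx <- numeric(nent)
  pos <- 0L
  for (k3 in 0:3) for (k2 in 0:3) for (k1 in 0:3) {
    idx <- (i0[, 3] + k3) * nd[1] * nd[2] + (i0[, 2] + k2) * nd[1] +
      (i0[, 1] + k1) + 1
    rng <- pos + seq_len(n)
    ii[rng] <- seq_len(n)
    jj[rng] <- as.integer(idx)
    xx[rng] <- wts[[1]][, k1 + 1] * wts[[2]][, k2 + 1] * wts[[3]][, k3 + 1]
    pos <- pos + n
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n, prod(nd)))
}

#' Evaluate the FFD displacement at arbitrary physical points
#' @param ffd a \linkS4class{BSplineFFD}
#' @param points n x 3 matrix of mm coordinates
#' @return n x 3 matrix of mm displacements
#' @export
ffdDisplacementAt <- function(ffd, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (max(abs(ffd@coefficients)) == 0)
    return(matrix(0, nrow(points), 3L))
  W <- ffdWeightMatrix(ffd, points)
  as.matrix(W %*% matrix(ffd@coefficients, ncol = 3L))
}

# Dense per-axis collocation matrix: rows are sample coordinates in lattice
# units, columns nodes.
bsplineCollocation1D <- function(u, nnode) {
  B <- matrix(0, length(u), nnode)
  i0 <- floor(u) - 1
  for (k in 0:3) {
    j <- i0 + k
    w <- bspline3(u - j)
    ok <- j >= 0 & j < nnode
    B[cbind(which(ok), j[ok] + 1)] <- w[ok]
  }
  B
}

#' Evaluate the FFD displacement on every voxel of an axis-aligned grid
#'
#' Uses the separable tensor-product structure of the lattice for speed;
#' requires the grid orientation to be the identity (falls back to pointwise
#' evaluation otherwise).
#'
#' @param ffd a \linkS4class{BSplineFFD}
#' @param grid a \linkS4class{VolumeGrid}
#' @return a 4D array (grid dim x 3) of mm displacements
#' @export
ffdDisplacementField <- function(ffd, grid) {
  d <- grid@dim
  if (max(abs(grid@orientation - diag(3))) > 1e-9) {
    u <- ffdDisplacementAt(ffd, gridPoints(grid))
    return(array(u, c(d, 3L)))
  }
  nd <- ffd@nodeDim
  B <- vector("list", 3L)
  for (a in 1:3) {
    x <- grid@origin[a] + grid@spacing[a] * (seq_len(d[a]) - 1)
    u <- (x - ffd@nodeOrigin[a]) / ffd@nodeSpacing[a]
    u <- pmin(pmax(u, 1), nd[a] - 2 - 1e-9)
    B[[a]] <- bsplineCollocation1D(u, nd[a])
  }
  out <- array(0, c(d, 3L))
  for (comp in 1:3) {
    A <- ffd@coefficients[, , , comp]
    t1 <- B[[1]] %*% matrix(A, nd[1], nd[2] * nd[3])        # n1 x (nc2 nc3)
    t1 <- aperm(array(as.matrix(t1), c(d[1], nd[2], nd[3])), c(2, 1, 3))
    t2 <- B[[2]] %*% matrix(t1, nd[2], d[1] * nd[3])        # n2 x (n1 nc3)
    t2 <- aperm(array(as.matrix(t2), c(d[2], d[1], nd[3])), c(3, 2, 1))
    t3 <- B[[3]] %*% matrix(t2, nd[3], d[1] * d[2])         # n3 x (n1 n2)
    out[, , , comp] <- aperm(array(as.matrix(t3), c(d[3], d[1], d[2])),
                             c(2, 3, 1))
  }
  out
}

# Solve the separable cubic-spline interpolation problem: find coefficients
# whose spline reproduces `values` at every node position of `ffd`.
# At integer lattice coordinates the cubic basis weights are (1/6, 2/3, 1/6),
# giving a tridiagonal system per line; edge rows use the clamped closure
# c[-1] = c[0].
ffdFitAtNodes <- function(ffd, values) {
  nd <- ffd@nodeDim
  solveAxis <- function(n) {
    M <- diag(2 / 3, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        M[i, i + 1] <- 1 / 6
        M[i + 1, i] <- 1 / 6
      }
      M[1, 1] <- M[n, n] <- 2 / 3 + 1 / 6
    }
    solve(M)
  }
  S <- lapply(nd, solveAxis)
  out <- array(0, c(nd, 3L))
  for (comp in 1:3) {
    A <- values[, , , comp]
    t1 <- S[[1]] %*% matrix(A, nd[1], nd[2] * nd[3])
    t1 <- aperm(array(as.matrix(t1), nd), c(2, 1, 3))
    t2 <- S[[2]] %*% matrix(t1, nd[2], nd[1] * nd[3])
    t2 <- aperm(array(as.matrix(t2), c(nd[2], nd[1], nd[3])), c(3, 2, 1))
    t3 <- S[[3]] %*% matrix(t2, nd[3], nd[1] * nd[2])
    out[, , , comp] <- aperm(array(as.matrix(t3), c(nd[3], nd[1], nd[2])),
                             c(2, 3, 1))
  }
  out
}

#' Refine an FFD onto a finer control lattice
#'
#' Builds a new lattice at the requested spacing and fits its coefficients
#' so the new spline interpolates the current displacement field exactly at
#' every new node position (separable tridiagonal solve).  Used between the
#' multi-resolution registration stages.
#'
#' @param ffd the current \linkS4class{BSplineFFD}
#' @param grid the fixed-image grid the lattice must cover
#' @param nodeSpacingMm target node spacing (mm)
#' @return a \linkS4class{BSplineFFD} on the finer lattice
#' @export
ffdRefine <- function(ffd, grid, nodeSpacingMm) {
  newFfd <- ffdLattice(grid, nodeSpacingMm)
  nd <- newFfd@nodeDim
  nodes <- as.matrix(expand.grid(seq_len(nd[1]) - 1, seq_len(nd[2]) - 1,
                                 seq_len(nd[3]) - 1))
  pts <- sweep(sweep(nodes, 2L, newFfd@nodeSpacing, "*"), 2L,
               newFfd@nodeOrigin, "+")
  vals <- ffdDisplacementAt(ffd, pts)
  newFfd@coefficients <- ffdFitAtNodes(newFfd, array(vals, c(nd, 3L)))
  newFfd
}

# ---- serialization ---------------------------------------------------------

#' Write a transform to JSON (plus a NIfTI coefficient volume for FFDs)
#'
#' Affines are stored as a 4 x 4 matrix plus centre in a JSON sidecar; FFD
#' stages as a JSON header with the lattice geometry and a 4D NIfTI
#' displacement-coefficient volume next to it.
#'
#' @param transform an \linkS4class{AffineTransform},
#'   \linkS4class{BSplineFFD} or \linkS4class{CompositeTransform}
#' @param path output path without extension
#' @return invisibly, the files written
#' @export
writeTransform <- function(transform, path) {
  files <- character()
  if (is(transform, "AffineTransform")) {
    m4 <- rbind(cbind(transform@matrix, transform@translation), c(0, 0, 0, 1))
    jsonlite::write_json(
      list(type = "affine", matrix4 = m4, center = transform@center),
      paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
    files <- paste0(path, ".json")
  } else if (is(transform, "BSplineFFD")) {
    coefFile <- paste0(path, "_coefficients.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(transform@coefficients), coefFile)
    jsonlite::write_json(
      list(type = "bspline_ffd", nodeOrigin = transform@nodeOrigin,
           nodeSpacing = transform@nodeSpacing,
           nodeDim = transform@nodeDim, coefficients = basename(coefFile)),
      paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
    files <- c(paste0(path, ".json"), coefFile)
  } else if (is(transform, "CompositeTransform")) {
    parts <- character()
    for (i in seq_along(transform@transforms)) {
      sub <- paste0(path, "_", i)
      files <- c(files, writeTransform(transform@transforms[[i]], sub))
      parts <- c(parts, basename(sub))
    }
    jsonlite::write_json(list(type = "composite", parts = parts),
                         paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE)
    files <- c(paste0(path, ".json"), files)
  } else stop("unsupported transform type")
  invisible(files)
}

#' Read a transform written by writeTransform
#' @param path the path given to \code{writeTransform} (without extension)
#' @return the reconstructed \linkS4class{SpatialTransform}
#' @export
readTransform <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (hdr$type == "affine") {
    m4 <- matrix(unlist(hdr$matrix4), 4L, 4L)
    affineTransform(m4[1:3, 1:3], m4[1:3, 4], unlist(hdr$center))
  } else if (hdr$type == "bspline_ffd") {
    coef <- RNifti::readNifti(file.path(dirname(path), hdr$coefficients))
    nd <- as.integer(hdr$nodeDim)
    new("BSplineFFD", nodeOrigin = as.numeric(hdr$nodeOrigin),
        nodeSpacing = as.numeric(hdr$nodeSpacing), nodeDim = nd,
        coefficients = array(as.numeric(coef), c(nd, 3L)))
  } else if (hdr$type == "composite") {
    parts <- lapply(hdr$parts, function(p)
      readTransform(file.path(dirname(path), p)))
    new("CompositeTransform", transforms = parts)
  } else stop("unknown transform type: ", hdr$type)
}
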
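#' @include AllClasses.R utils.R
NULL

# squared Euclidean distances between rows of x (n x d) and rows of
# c (k x d) -> n x k
.sqdist <- function(x, cent) {
  n2x <- rowSums(x * x)
  n2c <- rowSums(cent * cent)
  d2 <- outer(n2x, n2c, "+") - 2 * tcrossprod(x, cent)
  pmax(d2, 0)
}

#' K-Means clustering of colour triples (Lloyd iterations, k-means++ init)
#'
#' Classic Lloyd's algorithm on RGB points in [0, 1]: seeded k-means++
#' initialization, assignment of every point to its nearest centroid in
#' Euclidean colour distance, centroid update to cluster means, until
#' the maximum centroid movement drops below \code{tol} or
#' \code{maxIter} is reached. An empty cluster is re-seeded at the point
#' farthest from its assigned centroid. The per-iteration inertia trace
#' (sum of squared distances to the assigned centroid) is returned and
#' is non-increasing by construction.
#'
#' @param points numeric matrix (n x 3) of RGB triples (any n x d
#'   works).
#' @param k number of clusters, \code{1 <= k <= nrow(points)}.
#' @param seed integer seed for the initialization.
#' @param maxIter,tol termination controls.
#' @return list with \code{centroids} (k x d), \code{assignment}
#'   (integer n-vector), \code{inertia} (final sum of squared
#'   distances) and \code{inertiaTrace} (one value per Lloyd
#'   iteration).
#' @examples
#' pts <- matrix(runif(60), 20, 3)
#' fit <- kmeansFit(pts, k = 2, seed = 1)
#' fit$inertia
#' @export
kmeansFit <- function(points, k, seed = 1L, maxIter = 300L, tol = 1e-4) {
  points <- as.matrix(points)
  n <- nrow(points); k <- as.integer(k)
  if (k < 1L) stop("K must be >= 1")
  if (k > n) stop("K = ", k, " exceeds the number of points (", n, ")")
  cent <- withSeed(seed, {
    cc <- matrix(0, k, ncol(points))
    cc[1L, ] <- points[sample.int(n, 1L), ]
    if (k > 1L) {
      minD2 <- .sqdist(points, cc[1L, , drop = FALSE])[, 1L]
      for (j in 2:k) {
        pick <- if (sum(minD2) <= 0) sample.int(n, 1L)
                else sample.int(n, 1L, prob = minD2)
        cc[j, ] <- points[pick, ]
        minD2 <- pmin(minD2, .sqdist(points, cc[j, , drop = FALSE])[, 1L])
      }
    }
    cc
  })
  trace <- numeric(0)
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    d2 <- .sqdist(points, cent)
    assign <- max.col(-d2, ties.method = "first")
    pointD2 <- d2[cbind(seq_len(n), assign)]
    # re-seed empty clusters at the farthest point
    empty <- setdiff(seq_len(k), unique(assign))
    for (j in empty) {
      far <- which.max(pointD2)
      cent[j, ] <- points[far, ]
      assign[far] <- j
      pointD2[far] <- 0
    }
    trace <- c(trace, sum(pointD2))
    newCent <- rowsum(points, assign)
    cnt <- tabulate(assign, nbins = k)
    newCent <- newCent[order(as.integer(rownames(newCent))), , drop = FALSE]
    newCent <- newCent / cnt[cnt > 0L]
    full <- matrix(cent, k, ncol(points))
    full[sort(unique(assign)), ] <- newCent
    move <- sqrt(max(rowSums((full - cent)^2)))
    cent <- full
    if (move < tol) break
  }
  d2 <- .sqdist(points, cent)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  list(centroids = cent, assignment = assign, inertia = inertia,
       inertiaTrace = trace)
}

#' Flat-kernel Mean-Shift clustering of colour triples
#'
#' Nonparametric mode seeking: every seed is iteratively replaced by
#' the mean of all points within Euclidean distance \code{bandwidth}
#' (flat kernel) until its displacement falls below \code{tol}.
#' Converged modes closer than \code{bandwidth / 2} are merged (first
#' survivor wins, in seeding order), and every point is assigned to its
#' nearest surviving mode. Seeds are the occupied cells of a
#' bandwidth-sized grid (their point means), which keeps the procedure
#' deterministic given the input order and fast on tile-sized inputs.
#'
#' @param points numeric matrix (n x 3) of RGB triples.
#' @param bandwidth flat-kernel radius (> 0) in normalized colour units.
#' @param maxIter,tol termination controls of the mode iteration.
#' @return list with \code{modes} (m x d matrix) and \code{assignment}
#'   (integer n-vector).
#' @export
meanShiftFit <- function(points, bandwidth, maxIter = 300L, tol = 1e-4) {
  points <- as.matrix(points)
  if (!(bandwidth > 0)) stop("bandwidth must be > 0")
  n <- nrow(points)
  bw2 <- bandwidth^2
  # binned seeding: one seed per occupied grid cell, in first-occurrence
  # order
  cells <- apply(floor(t(points) / bandwidth), 2L, paste, collapse = ",")
  firsts <- !duplicated(cells)
  seeds <- rowsum(points, cells, reorder = FALSE)
  seeds <- seeds / as.vector(table(factor(cells, levels = unique(cells))))
  modes <- matrix(0, nrow(seeds), ncol(points))
  for (s in seq_len(nrow(seeds))) {
    m <- seeds[s, ]
    for (it in seq_len(maxIter)) {
      d2 <- .sqdist(points, matrix(m, 1L))[, 1L]
      nb <- d2 <= bw2
      newM <- colMeans(points[nb, , drop = FALSE])
      if (sqrt(sum((newM - m)^2)) < tol) { m <- newM; break }
      m <- newM
    }
    modes[s, ] <- m
  }
  # merge modes closer than bandwidth / 2, keeping the earlier one
  keep <- logical(nrow(modes))
  for (s in seq_len(nrow(modes))) {
    if (!any(keep)) { keep[s] <- TRUE; next }
    d2 <- .sqdist(modes[keep, , drop = FALSE],
                  matrix(modes[s, ], 1L))[, 1L]
    if (all(d2 > (bandwidth / 2)^2)) keep[s] <- TRUE
  }
  modes <- modes[keep, , drop = FALSE]
  assign <- max.col(-.sqdist(points, modes), ties.method = "first")
  list(modes = modes, assignment = assign)
}

#' Colour-quantize one tile by K-Means or Mean-Shift
#'
#' The pixels of a single image are treated as independent RGB triples
#' and clustered per \code{params}; every pixel is then replaced by its
#' centroid (K-Means) or mode (Mean-Shift) colour, preserving the image
#' shape. With K-Means and \code{K = 8} the output contains at most 8
#' distinct colours; Mean-Shift determines its own palette size from
#' the bandwidth.
#'
#' @param img \code{H x W x 3} array in [0, 1].
#' @param params a [ClusterParams-class].
#' @return a [QuantizedImage-class].
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' q <- quantizeImage(img, clusterParams("KM", k = 8))
#' nrow(unique(matrix(q@pixels, ncol = 3)))  # <= 8
#' @export
quantizeImage <- function(img, params) {
  stopifnot(is(params, "ClusterParams"))
  validObject(params)
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L) stop("img must be H x W x 3")
  pts <- matrix(img, d[1L] * d[2L], 3L)
  fit <- if (params@method == "KM")
    kmeansFit(pts, params@k, seed = params@seed,
              maxIter = params@maxIter, tol = params@tol)
  else
    meanShiftFit(pts, params@bandwidth, maxIter = params@maxIter,
                 tol = params@tol)
  palette <- if (params@method == "KM") fit$centroids else fit$modes
  recon <- palette[fit$assignment, , drop = FALSE]
  new("QuantizedImage",
      pixels = array(clamp01(recon), dim = d),
      palette = clamp01(palette),
      assignment = matrix(fit$assignment, d[1L], d[2L]))
}

#' @describeIn quantizeTiles quantize every tile of a TileSet
#'   independently (per-image fits; labels and magnification preserved).
#' @export
setMethod("quantizeTiles", signature("TileSet", "ClusterParams"),
  function(x, params) {
    images <- lapply(tileImages(x),
                     function(im) quantizeImage(im, params)@pixels)
    new("TileSet", images = images, labels = tileLabels(x),
        magnification = magnification(x))
  })
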
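test_that("K-Means closed forms: duplicates, K = 1, and guards", {
  pts <- matrix(rep(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), times = 15),
                ncol = 3, byrow = TRUE)   # two distinct colour rows
  fit <- kmeansFit(pts, 2, seed = 1L)
  expect_equal(sort(unique(fit$centroids[, 1])), c(0.2, 0.8))
  expect_equal(fit$inertia, 0)

  set.seed(4)
  pts <- matrix(runif(45), 15, 3)
  f1 <- kmeansFit(pts, 1, seed = 1L)
  expect_equal(as.vector(f1$centroids), colMeans(pts))
  expect_true(all(f1$assignment == 1L))

  expect_error(kmeansFit(pts, 16, seed = 1L), "exceeds")
  expect_error(kmeansFit(pts, 0), ">= 1")
})

test_that("K-Means recovers well-separated Gaussian colour modes", {
  set.seed(123)
  truth <- c(0.15, 0.5, 0.85)
  pts <- do.call(rbind, lapply(truth, function(m)
    matrix(rnorm(20 * 3, m, 0.02), 20, 3)))
  fit <- kmeansFit(pts, 3, seed = 11L)
  cent <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_lt(max(abs(cent - matrix(truth, 3, 3))), 0.05)
  # exhaustive nearest-centroid oracle: every point sits with its
  # closest recovered centroid
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums((fit$centroids -
                     matrix(pts[i, ], nrow(fit$centroids), 3,
                            byrow = TRUE))^2)
    expect_equal(fit$assignment[i], which.min(d2))
  }
})

test_that("K-Means inertia trace is non-increasing and seeds reproduce", {
  set.seed(7)
  pts <- matrix(runif(300), 100, 3)
  fit <- kmeansFit(pts, 5, seed = 3L)
  expect_true(all(diff(fit$inertiaTrace) <= 1e-10))
  fit2 <- kmeansFit(pts, 5, seed = 3L)
  expect_identical(fit2$centroids, fit$centroids)
  expect_identical(fit2$assignment, fit$assignment)
  # independent cross-check: our converged inertia is no worse than a
  # generously restarted reference implementation allows (local optima
  # permitted, but same objective scale)
  ref <- stats::kmeans(pts, 5, nstart = 10)
  expect_lt(fit$inertia, ref$tot.withinss * 1.5 + 1e-9)
})

test_that("Mean-Shift finds blob means, merges modes and handles limits", {
  set.seed(21)
  blobA <- matrix(rnorm(60, 0.2, 0.01), 20, 3)
  blobB <- matrix(rnorm(60, 0.8, 0.01), 20, 3)
  pts <- rbind(blobA, blobB)
  ms <- meanShiftFit(pts, 0.15)
  expect_equal(nrow(ms$modes), 2L)
  got <- ms$modes[order(ms$modes[, 1]), ]
  expect_lt(max(abs(got - rbind(colMeans(blobA), colMeans(blobB)))), 1e-3)
  expect_true(all(ms$assignment[1:20] == ms$assignment[1]))
  expect_true(ms$assignment[1] != ms$assignment[21])

  # bandwidth beyond the data diameter: single global mean mode
  ms1 <- meanShiftFit(pts, 5)
  expect_equal(nrow(ms1$modes), 1L)
  expect_lt(max(abs(ms1$modes[1, ] - colMeans(pts))), 1e-3)

  # all-identical points: one mode equal to that point
  same <- matrix(0.4, 10, 3)
  msSame <- meanShiftFit(same, 0.2)
  expect_equal(nrow(msSame$modes), 1L)
  expect_equal(as.vector(msSame$modes[1, ]), rep(0.4, 3))

  expect_error(meanShiftFit(pts, 0), "bandwidth")
})

test_that("quantizeImage bounds the palette and fixes already-quantized input", {
  set.seed(9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  q <- quantizeImage(img, clusterParams("KM", k = 8L, seed = 2L))
  expect_identical(dim(q@pixels), dim(img))
  expect_lte(nrow(unique(matrix(q@pixels, ncol = 3))), 8L)
  expect_true(validObject(q))

  # an image with <= K colours is a zero-inertia fixed point
  few <- array(sample(c(0.1, 0.5, 0.9), 16 * 16 * 1, replace = TRUE),
               c(16, 16, 1))[, , c(1, 1, 1)]
  qf <- quantizeImage(few, clusterParams("KM", k = 8L, seed = 5L))
  expect_equal(qf@pixels, few, tolerance = 1e-8)

  # constant image under Mean-Shift is untouched
  cimg <- array(0.4, c(8, 8, 3))
  qc <- quantizeImage(cimg, clusterParams("MS", bandwidth = 0.2))
  expect_identical(qc@pixels, cimg)

  # Mean-Shift idempotence in its intended regime (palette modes
  # separated by more than the bandwidth): re-quantizing changes nothing
  tile <- tileImages(generateSyntheticTiles(
    syntheticTileParams(nImages = 1L, noiseSd = 0, seed = 13L)))[[1L]]
  qm <- quantizeImage(tile, clusterParams("MS", bandwidth = 0.2))
  qm2 <- quantizeImage(qm@pixels, clusterParams("MS", bandwidth = 0.2))
  expect_equal(qm2@pixels, qm@pixels, tolerance = 1e-6)
})

test_that("quantizeTiles maps every tile and preserves labels", {
  ds <- generateSyntheticTiles(syntheticTileParams(nImages = 4L, seed = 8L))
  qs <- quantizeTiles(ds, clusterParams("KM", k = 4L, seed = 1L))
  expect_identical(tileLabels(qs), tileLabels(ds))
  for (im in tileImages(qs))
    expect_lte(nrow(unique(matrix(im, ncol = 3))), 4L)
})
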
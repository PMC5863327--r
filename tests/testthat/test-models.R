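tableRows <- list(c(24L, 128L), c(32L, 96L), c(48L, 64L), c(64L, 48L),
                  c(96L, 32L), c(128L, 24L))
tableCounts <- c(58280L, 52904L, 47528L, 44840L, 42152L, 40808L)

test_that("sequence reshape enforces the exact factorization", {
  expect_equal(reshapeToSequence(3072, 24, 128), c(ts = 24L, id = 128L))
  expect_equal(reshapeToSequence(3072, 64, 48), c(ts = 64L, id = 48L))
  expect_error(reshapeToSequence(3072, 50, 60), "3000")
  expect_error(modelSpec(2, ts = 50, id = 60), "3072")
  expect_error(modelSpec(3, ts = 50, id = 60), "512")
  expect_error(modelSpec(2), "explicit")
})

test_that("Model 1 reproduces the documented spatial chain and flatten width", {
  net <- buildModel(modelSpec(1), seed = 1L)
  s <- summary(net)
  expect_equal(s$output[s$layer %in% c("conv", "pool")],
               c("32 x 32 x 16", "32 x 32 x 16", "16 x 16 x 16",
                 "16 x 16 x 16", "8 x 8 x 16", "8 x 8 x 16",
                 "4 x 4 x 16", "4 x 4 x 16"))
  expect_equal(s$output[s$layer == "flatten"], "256")
  # forward shape contract
  imgs <- lapply(1:5, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  sc <- networkScores(net, imgs)
  expect_identical(dim(sc), c(5L, 2L))
})

test_that("Model 2 hits every published parameter total under both realizations", {
  counts <- vapply(tableRows, function(p)
    countParameters(buildModel(modelSpec(2, ts = p[1], id = p[2]),
                               seed = 1L)), integer(1))
  expect_identical(counts, tableCounts)
  # the stacked alternative is parameter-count identical
  expect_identical(
    countParameters(buildModel(modelSpec(2, ts = 64, id = 48,
                                         l2Kind = "stacked"), seed = 1L)),
    44840L)
  # analytic decomposition: L-1 + two 42-unit blocks + dense chain
  for (i in seq_along(tableRows)) {
    id <- tableRows[[i]][2]
    expect_equal(lstmParamCount(id, 42) + 2L * lstmParamCount(42, 42) +
                   denseParamCount(42, 22) + denseParamCount(22, 2),
                 tableCounts[i])
  }
  # finite-difference law between consecutive rows
  for (i in 1:5) {
    dID <- tableRows[[i]][2] - tableRows[[i + 1]][2]
    expect_equal(tableCounts[i] - tableCounts[i + 1], 4L * 42L * dID)
  }
})

test_that("Model 3 exposes the 512 bottleneck, 65-unit dense and score shape", {
  net <- buildModel(modelSpec(3, ts = 32, id = 16), seed = 2L)
  s <- summary(net)
  dense <- s$output[s$layer == "dense"]
  expect_equal(dense, c("512", "65", "2"))
  expect_equal(s$output[s$layer == "pool"], "16 x 16 x 32")
  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_identical(dim(networkScores(net, imgs)), c(3L, 2L))
})

test_that("builders are seed-deterministic and evaluation ignores drop-out", {
  a <- buildModel(modelSpec(1), seed = 7L)
  b <- buildModel(modelSpec(1), seed = 7L)
  expect_identical(a@layers, b@layers)
  c2 <- buildModel(modelSpec(1), seed = 8L)
  expect_false(identical(a@layers, c2@layers))
  imgs <- lapply(1:4, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_identical(networkScores(a, imgs), networkScores(a, imgs))
})

test_that("counting parameters enumerates the actual tensors", {
  # oracle: walk the parameter tensors directly and sum their lengths
  for (spec in list(modelSpec(1), modelSpec(2, ts = 96, id = 32),
                    modelSpec(3, ts = 16, id = 32))) {
    net <- buildModel(spec, seed = 1L)
    brute <- 0L
    for (l in net@layers) {
      for (nm in c("W", "b", "Wx", "Wh"))
        if (!is.null(l[[nm]])) brute <- brute + length(l[[nm]])
      for (side in c("fwd", "bwd"))
        if (!is.null(l[[side]]))
          brute <- brute + sum(lengths(l[[side]]))
    }
    expect_identical(countParameters(net), brute)
  }
  # empty network counts zero
  empty <- new("TileNet", layers = list(), spec = modelSpec(1),
               inputShape = c(32L, 32L, 3L), svmHead = list(),
               trained = FALSE)
  expect_identical(countParameters(empty), 0L)
})

test_that("invalid conv widths are rejected", {
  expect_error(buildModel(modelSpec(1, convMaps = c(8L, 8L))), "5 conv")
  expect_error(buildModel(modelSpec(1, convMaps = rep(8L, 5L))),
               "16 feature maps")
  expect_error(buildModel(modelSpec(3, ts = 32, id = 16,
                                    convMaps = rep(16L, 4L))), "3 conv")
})
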
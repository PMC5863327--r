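test_that("synthetic generator respects the imbalance, range and determinism contracts", {
  p <- syntheticTileParams(nImages = 100L, malignantFraction = 0.686,
                           seed = 7L)
  ds <- generateSyntheticTiles(p)
  expect_equal(nTiles(ds), 100L)
  nMal <- sum(tileLabels(ds) == "malignant")
  # binomial draw around n * p = 68.6; stay within a generous seeded band
  expect_gte(nMal, qbinom(0.0005, 100, 0.686))
  expect_lte(nMal, qbinom(0.9995, 100, 0.686))
  # exact count reproducible for the seed
  ds2 <- generateSyntheticTiles(p)
  expect_identical(sum(tileLabels(ds2) == "malignant"), nMal)
  expect_identical(tileImages(ds2), tileImages(ds))
  expect_identical(tileLabels(ds2), tileLabels(ds))

  # noise-free tiles stay in range and keep the 32 x 32 x 3 shape
  ds0 <- generateSyntheticTiles(syntheticTileParams(nImages = 10L,
                                                    malignantFraction = 0.5,
                                                    noiseSd = 0, seed = 2L))
  expect_equal(nTiles(ds0), 10L)
  for (im in tileImages(ds0)) {
    expect_identical(dim(im), c(32L, 32L, 3L))
    expect_true(min(im) >= 0 && max(im) <= 1)
  }
})

test_that("generator rejects invalid parameters", {
  expect_error(syntheticTileParams(malignantFraction = 1.2), "0, 1")
  expect_error(syntheticTileParams(nImages = 0), "positive")
  expect_error(syntheticTileParams(radiusRange = c(0.2, 3)), "1 pixel")
})

test_that("noise-free disjoint-colour tiles are pixel-mean separable", {
  ds <- generateSyntheticTiles(syntheticTileParams(nImages = 120L,
                                                   noiseSd = 0, seed = 31L))
  pred <- thresholdOracle(ds)
  expect_equal(mean(pred == tileLabels(ds)), 1)
})

test_that("TileSet round-trips through a PNG directory with manifest", {
  ds <- generateSyntheticTiles(syntheticTileParams(nImages = 6L, seed = 3L))
  d <- withr::local_tempdir()
  writeTileSet(ds, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- readTileSet(d)
  expect_equal(nTiles(back), 6L)
  expect_identical(tileLabels(back), tileLabels(ds))
  # 8-bit PNG quantization: within half a grey level
  expect_lt(max(abs(unlist(tileImages(back)) - unlist(tileImages(ds)))),
            1 / 255)
})

test_that("directory loading resizes, labels from structure and broadcasts grayscale", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "benign")); dir.create(file.path(root, "malignant"))
  mk <- function(path, h, w, gray = FALSE) {
    img <- if (gray) EBImage::Image(matrix(runif(h * w), h, w))
           else EBImage::Image(array(runif(h * w * 3), c(h, w, 3)),
                               colormode = "Color")
    EBImage::writeImage(img, path)
  }
  set.seed(5)
  mk(file.path(root, "benign", "a.png"), 760, 460)
  mk(file.path(root, "benign", "b.png"), 64, 48)
  mk(file.path(root, "malignant", "c.png"), 100, 80)
  mk(file.path(root, "malignant", "d.jpg"), 40, 40)
  mk(file.path(root, "malignant", "gray.png"), 50, 60, gray = TRUE)
  ds <- loadImageDirectory(root, "flat")
  expect_equal(nTiles(ds), 5L)
  expect_equal(as.vector(table(tileLabels(ds))), c(2L, 3L))
  for (im in tileImages(ds))
    expect_identical(dim(im), c(32L, 32L, 3L))
  # grayscale file: three identical channels
  gidx <- which(vapply(tileImages(ds), function(im)
    identical(im[, , 1], im[, , 2]) && identical(im[, , 2], im[, , 3]),
    logical(1)))
  expect_true(length(gidx) >= 1L)
  # empty class errors
  expect_error(loadImageDirectory(withr::local_tempdir(), "flat"),
               "no readable images")
})

test_that("stratified split preserves proportions, is disjoint, exhaustive and seeded", {
  ds <- constantTileSet(c(rep("malignant", 70), rep("benign", 30)))
  sp <- stratifiedSplit(ds, 0.3, seed = 9L)
  expect_equal(sum(tileLabels(sp$test) == "malignant"), 21L)
  expect_equal(sum(tileLabels(sp$test) == "benign"), 9L)
  expect_equal(nTiles(sp$train) + nTiles(sp$test), 100L)
  # membership disjoint/exhaustive via the tile shades (all distinct)
  shTr <- vapply(tileImages(sp$train), function(x) x[1], numeric(1))
  shTe <- vapply(tileImages(sp$test), function(x) x[1], numeric(1))
  expect_length(intersect(shTr, shTe), 0L)
  expect_setequal(c(shTr, shTe),
                  vapply(tileImages(ds), function(x) x[1], numeric(1)))
  # same seed -> identical membership
  sp2 <- stratifiedSplit(ds, 0.3, seed = 9L)
  expect_identical(tileImages(sp2$test), tileImages(sp$test))

  # 4 + 4 at 0.5 -> 2 + 2
  ds8 <- constantTileSet(rep(c("benign", "malignant"), each = 4))
  sp8 <- stratifiedSplit(ds8, 0.5, seed = 1L)
  expect_equal(as.vector(table(tileLabels(sp8$test))), c(2L, 2L))

  # class too small to stratify
  ds3 <- constantTileSet(c("benign", "malignant", "malignant"))
  expect_error(stratifiedSplit(ds3, 0.3, seed = 1L), "at least 2")
  expect_error(stratifiedSplit(ds8, 1.2, seed = 1L), "\\(0, 1\\)")
})

test_that("TileSet validity rejects malformed images", {
  expect_error(TileSet(list(array(2, c(32, 32, 3))), "benign"),
               "invariant")
  expect_error(TileSet(list(array(0.5, c(32, 32, 2))), "benign"),
               "invariant")
  expect_error(TileSet(list(array(0.5, c(32, 32, 3))), "weird"),
               "benign")
})
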
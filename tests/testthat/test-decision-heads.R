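makeSeparable <- function(n, seed) {
  generateSyntheticTiles(syntheticTileParams(nImages = n, noiseSd = 0,
                                             seed = seed))
}

test_that("epochs = 0 returns the untouched network and empty history", {
  ds <- makeSeparable(12, 4L)
  sp <- stratifiedSplit(ds, 0.3, seed = 1L)
  net <- buildModel(modelSpec(1), seed = 1L)
  res <- trainSoftmax(net, sp$train, sp$test, trainConfig(epochs = 0L))
  expect_identical(res$net@layers, net@layers)
  expect_equal(nrow(res$history), 0L)
})

test_that("training is seed-deterministic and the loss trend decreases", {
  ds <- makeSeparable(40, 6L)
  sp <- stratifiedSplit(ds, 0.3, seed = 2L)
  net <- buildModel(modelSpec(1), seed = 5L)
  cfg <- trainConfig(epochs = 4L, seed = 5L)
  a <- trainSoftmax(net, sp$train, sp$test, cfg)
  b <- trainSoftmax(net, sp$train, sp$test, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$net@layers, b$net@layers)
  expect_equal(names(a$history),
               c("epoch", "train_acc", "test_acc", "train_loss",
                 "test_loss", "train_mcc", "test_mcc"))
  # on this separable task the smoothed loss must not increase overall
  expect_lt(tail(a$history$train_loss, 1), a$history$train_loss[1])
})

test_that("hinge-loss end-to-end training also learns the separable task", {
  ds <- makeSeparable(40, 16L)
  sp <- stratifiedSplit(ds, 0.3, seed = 2L)
  net <- buildModel(modelSpec(1), seed = 3L)
  res <- trainSoftmax(net, sp$train, sp$test,
                      trainConfig(epochs = 6L, seed = 3L), loss = "hinge")
  expect_gte(tail(res$history$train_acc, 1), 90)
})

test_that("the SVM head reproduces the grid-search optimum on the toy set", {
  X <- matrix(rep(c(0, 1, 0, -1), 20), ncol = 2, byrow = TRUE)
  y <- rep(c(1, -1), 20)
  oracle <- svmGridOracle(X, y, C = 1)
  # direct minimization puts all weight on the second coordinate
  expect_equal(oracle$W, c(0, 1))
  expect_equal(oracle$objective, 0.5)
  labels <- ifelse(y == 1, "malignant", "benign")
  head <- deepTiles:::.fitLinearSvm(X, labels, C = 1)
  fittedObj <- svmObjective(head$W, X, y, C = 1, b = head$b)
  expect_lt(abs(fittedObj - oracle$objective), 0.05)
  # decision boundary is sign(x2)
  pred <- sign(X %*% head$W + head$b)
  expect_equal(as.vector(pred), y)
  # the fitted objective never exceeds the W = 0 value C * n
  expect_lte(fittedObj, 1 * nrow(X))
})

test_that("SVM head limits: separability, vanishing C, single class", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
  labels <- rep(c("malignant", "benign"), each = 20)
  head <- deepTiles:::.fitLinearSvm(X, labels, C = 1)
  pred <- ifelse(as.vector(X %*% head$W + head$b) > 0, "malignant",
                 "benign")
  expect_equal(pred, labels)
  # margins >= 1 achievable: essentially zero slack at the optimum
  y <- ifelse(labels == "malignant", 1, -1)
  obj <- svmObjective(head$W, X, y, C = 1, b = head$b)
  expect_lt(obj, 0.5 * sum(head$W^2) + 0.1)

  # vanishing C drives the weights (and hence every margin) to zero
  tiny <- deepTiles:::.fitLinearSvm(X, labels, C = 1e-6)
  expect_lt(sqrt(sum(tiny$W^2)), 1e-3)
  expect_lt(max(abs(as.vector(X %*% tiny$W + tiny$b))), 1e-2)

  expect_error(deepTiles:::.fitLinearSvm(X, rep("malignant", 40), C = 1),
               "single-class")
})

test_that("fitSvmHead requires a trained network and flips the decision kind", {
  ds <- makeSeparable(30, 9L)
  sp <- stratifiedSplit(ds, 0.3, seed = 3L)
  net <- buildModel(modelSpec(1), seed = 2L)
  expect_error(fitSvmHead(net, sp$train), "train the network")
  tr <- trainSoftmax(net, sp$train, sp$test, trainConfig(epochs = 3L,
                                                         seed = 2L))
  withHead <- fitSvmHead(tr$net, sp$train, C = 1)
  expect_equal(withHead@spec@decision, "svm")
  pred <- predictTiles(withHead, sp$test)
  expect_s3_class(pred, "factor")
  expect_equal(levels(pred), c("benign", "malignant"))
  expect_length(pred, nTiles(sp$test))
})

test_that("prediction is total and ties break to benign", {
  ds <- makeSeparable(12, 10L)
  net <- buildModel(modelSpec(1), seed = 1L)
  pred <- predictTiles(net, ds)
  expect_false(anyNA(pred))
  expect_length(pred, 12L)
  # symmetric scores -> benign (argmax tie rule)
  expect_identical(deepTiles:::.scoresToClass(matrix(c(1, 1), 1, 2)), 1L)
  expect_identical(deepTiles:::.scoresToClass(matrix(c(0.3, 0.9), 1, 2)),
                   2L)
  # zero SVM margin -> benign
  netSvm <- net
  netSvm@trained <- TRUE
  netSvm@spec@decision <- "svm"
  netSvm@svmHead <- list(W = rep(0, 256), b = 0, C = 1)
  expect_true(all(predictTiles(netSvm, ds) == "benign"))
})
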
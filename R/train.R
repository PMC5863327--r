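#' @include AllClasses.R models.R metrics.R
NULL

# ---- Adam optimizer state over the network's parameter tensors ----

.adamInit <- function(net) {
  lapply(net@layers, function(l) {
    nms <- .layerParamNames(l)
    if (!length(nms)) return(NULL)
    sapply(nms, function(nm) {
      z <- .layerGetParam(l, nm) * 0
      list(m = z, v = z)
    }, simplify = FALSE)
  })
}

.adamStep <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net@layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in .layerParamNames(net@layers[[i]])) {
      gi <- g[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gi
      st$v <- beta2 * st$v + (1 - beta2) * gi * gi
      mHat <- st$m / (1 - beta1^t)
      vHat <- st$v / (1 - beta2^t)
      p <- .layerGetParam(net@layers[[i]], nm)
      net@layers[[i]] <- .layerSetParam(net@layers[[i]], nm,
                                        p - lr * mHat / (sqrt(vHat) + eps))
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# evaluate scores in memory-bounded chunks; returns (B x 2) matrix
.scoreTiles <- function(net, images, chunk = 64L) {
  n <- length(images)
  out <- matrix(0, n, 2L)
  for (s in seq(1L, n, chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    out[idx, ] <- .netForward(net, .tilesToArray(images[idx]),
                              training = FALSE)$scores
  }
  out
}

.featureTiles <- function(net, images, chunk = 64L) {
  n <- length(images)
  rows <- vector("list", length(seq(1L, n, chunk)))
  k <- 0L
  for (s in seq(1L, n, chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    k <- k + 1L
    rows[[k]] <- .netForward(net, .tilesToArray(images[idx]),
                             training = FALSE)$penultimate
  }
  do.call(rbind, rows)
}

# argmax over score rows; exact ties break to benign (class 1)
.scoresToClass <- function(scores) {
  ifelse(scores[, 2L] > scores[, 1L], 2L, 1L)
}

.evalSet <- function(net, ds) {
  scores <- .scoreTiles(net, tileImages(ds))
  y <- as.integer(tileLabels(ds))          # benign = 1, malignant = 2
  m <- apply(scores, 1L, max)
  lse <- m + log(exp(scores[, 1L] - m) + exp(scores[, 2L] - m))
  loss <- mean(lse - scores[cbind(seq_len(nrow(scores)), y)])
  pred <- .scoresToClass(scores)
  cc <- confusionCounts(tileLabels(ds),
                        factor(c("benign", "malignant")[pred],
                               levels = c("benign", "malignant")))
  list(acc = 100 * mean(pred == y), loss = loss,
       mcc = .mccSafe(cc@tp, cc@fp, cc@tn, cc@fn))
}

#' Train a network with the softmax cross-entropy decision layer
#'
#' Mini-batch Adam training of the full layer chain, minimizing the
#' mean cross-entropy of the softmax class probabilities (or, with
#' \code{loss = "hinge"}, the soft-margin hinge loss on the score
#' difference -- the end-to-end analogue of the SVM decision layer).
#' After every epoch the train and test accuracy, loss and Matthews
#' correlation coefficient are recorded, mirroring the three learning
#' curves the package plots. Fully seeded: the same configuration
#' produces identical histories on a single CPU thread. Training aborts
#' with a diagnostic if the loss turns non-finite.
#'
#' @param net a freshly built [TileNet-class] (softmax head).
#' @param train,test [TileSet-class] train and held-out test parts.
#' @param cfg a [TrainConfig-class].
#' @param loss \code{"softmax"} (cross-entropy, default) or
#'   \code{"hinge"}.
#' @return list with \code{net} (trained [TileNet-class]) and
#'   \code{history} (data.frame with columns epoch, train_acc,
#'   test_acc, train_loss, test_loss, train_mcc, test_mcc).
#'   \code{epochs = 0} returns the untouched network and an empty
#'   history.
#' @export
trainSoftmax <- function(net, train, test, cfg,
                         loss = c("softmax", "hinge")) {
  stopifnot(is(net, "TileNet"), is(train, "TileSet"), is(test, "TileSet"),
            is(cfg, "TrainConfig"))
  loss <- match.arg(loss)
  emptyHist <- data.frame(epoch = integer(), train_acc = numeric(),
                          test_acc = numeric(), train_loss = numeric(),
                          test_loss = numeric(), train_mcc = numeric(),
                          test_mcc = numeric())
  if (cfg@epochs == 0L) return(list(net = net, history = emptyHist))
  y <- as.integer(tileLabels(train))
  n <- nTiles(train)
  images <- tileImages(train)
  state <- .adamInit(net)
  tAdam <- 0L
  hist <- vector("list", cfg@epochs)
  net <- withSeed(stageSeed(cfg@seed, "train"), {
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, cfg@batchSize)) {
        idx <- ord[s:min(n, s + cfg@batchSize - 1L)]
        B <- length(idx)
        fw <- .netForward(net, .tilesToArray(images[idx]), training = TRUE)
        sc <- fw$scores
        if (loss == "softmax") {
          m <- apply(sc, 1L, max)
          e <- exp(sc - m)
          P <- e / rowSums(e)
          batchLoss <- mean(-log(pmax(P[cbind(seq_len(B), y[idx])],
                                      1e-300)))
          dsc <- P
          dsc[cbind(seq_len(B), y[idx])] <-
            dsc[cbind(seq_len(B), y[idx])] - 1
          dsc <- dsc / B
        } else {
          ys <- ifelse(y[idx] == 2L, 1, -1)     # malignant = +1
          margin <- ys * (sc[, 2L] - sc[, 1L])
          batchLoss <- mean(pmax(0, 1 - margin))
          active <- (margin < 1)
          dsc <- matrix(0, B, 2L)
          dsc[, 2L] <- -ys * active / B
          dsc[, 1L] <- ys * active / B
        }
        if (!is.finite(batchLoss))
          stop("training diverged: non-finite loss at epoch ", ep,
               " (reduce the learning rate)")
        grads <- .netBackward(net, fw$caches, dsc)
        tAdam <- tAdam + 1L
        upd <- .adamStep(net, grads, state, tAdam, cfg@learningRate)
        net <- upd$net
        state <- upd$state
      }
      trainEv <- .evalSet(net, train)
      testEv <- .evalSet(net, test)
      hist[[ep]] <- data.frame(epoch = ep,
                               train_acc = trainEv$acc,
                               test_acc = testEv$acc,
                               train_loss = trainEv$loss,
                               test_loss = testEv$loss,
                               train_mcc = trainEv$mcc,
                               test_mcc = testEv$mcc)
    }
    net
  })
  net@trained <- TRUE
  list(net = net, history = do.call(rbind, hist))
}

# fit a linear soft-margin SVM; returns list(W, b, C) oriented so that
# a positive margin means malignant
.fitLinearSvm <- function(features, labels, C) {
  labels <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (length(unique(labels)) < 2L)
    stop("cannot fit the SVM head on single-class training data")
  fit <- e1071::svm(x = features, y = labels, kernel = "linear",
                    cost = C, scale = FALSE)
  W <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dv <- as.vector(features %*% W + b)
  pred <- stats::predict(fit, features)
  agree <- sum(sign(dv) * ifelse(pred == "malignant", 1, -1))
  if (agree < 0) { W <- -W; b <- -b }
  list(W = W, b = b, C = C)
}

#' Fit the SVM decision head on extracted features
#'
#' Extracts the penultimate-layer activation vector of every training
#' tile (drop-out inactive) from a softmax-trained network and fits a
#' linear soft-margin SVM with labels \eqn{y \in \{-1, +1\}}
#' (malignant = +1) and penalty \code{C}. Prediction with the fitted
#' head is the sign of the margin; an exact zero margin maps to benign.
#'
#' @param net a trained [TileNet-class].
#' @param train a [TileSet-class]; both classes must be present.
#' @param C soft-margin penalty (default 1).
#' @return the network with the fitted SVM head attached (its
#'   \code{spec@decision} switched to \code{"svm"}).
#' @export
fitSvmHead <- function(net, train, C = 1) {
  stopifnot(is(net, "TileNet"), is(train, "TileSet"))
  if (!net@trained)
    stop("train the network (softmax regime) before fitting the SVM head")
  features <- .featureTiles(net, tileImages(train))
  net@svmHead <- .fitLinearSvm(features, tileLabels(train), C)
  net@spec@decision <- "svm"
  net
}

#' Predict benign / malignant labels
#'
#' Softmax head: argmax of the class scores. SVM head: sign of the
#' fitted linear margin on the penultimate features. In both regimes an
#' exact tie (equal scores, zero margin) deterministically yields
#' benign, favouring the no-disease label.
#'
#' @param net a trained [TileNet-class].
#' @param x a [TileSet-class] or list of \code{32 x 32 x 3} arrays.
#' @return factor of predicted labels (levels benign, malignant).
#' @export
predictTiles <- function(net, x) {
  images <- if (is(x, "TileSet")) tileImages(x) else x
  if (net@spec@decision == "svm" && length(net@svmHead)) {
    f <- .featureTiles(net, images)
    margin <- as.vector(f %*% net@svmHead$W + net@svmHead$b)
    pred <- ifelse(margin > 0, 2L, 1L)
  } else {
    pred <- .scoresToClass(.scoreTiles(net, images))
  }
  factor(c("benign", "malignant")[pred], levels = c("benign", "malignant"))
}

#' Raw decision-layer scores
#'
#' Forward pass through the chain in evaluation mode (drop-out
#' inactive), returning the two end-layer scores per tile (columns:
#' benign, malignant).
#'
#' @param net a [TileNet-class].
#' @param x a [TileSet-class] or list of \code{32 x 32 x 3} arrays.
#' @return numeric matrix (n x 2).
#' @export
networkScores <- function(net, x) {
  images <- if (is(x, "TileSet")) tileImages(x) else x
  .scoreTiles(net, images)
}

#' Write an epoch history to CSV
#'
#' @param history the history data.frame from [trainSoftmax()].
#' @param file output CSV path.
#' @return invisibly, the file path.
#' @export
exportHistory <- function(history, file) {
  utils::write.csv(history, file, row.names = FALSE)
  invisible(file)
}

#' Plot the three learning-curve panels
#'
#' Accuracy, loss and MCC against the epoch, train and test overlaid,
#' written to a PNG.
#'
#' @param history the history data.frame from [trainSoftmax()].
#' @param file output PNG path.
#' @return invisibly, the file path.
#' @export
plotHistory <- function(history, file) {
  grDevices::png(file, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  panels <- list(
    list(c("train_acc", "test_acc"), "Accuracy (%)"),
    list(c("train_loss", "test_loss"), "Loss"),
    list(c("train_mcc", "test_mcc"), "MCC"))
  for (p in panels) {
    cols <- p[[1L]]
    graphics::matplot(history$epoch, history[, cols], type = "l",
                      lty = 1, col = c("steelblue", "firebrick"),
                      xlab = "epoch", ylab = p[[2L]])
    graphics::legend("bottomright", legend = c("train", "test"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  }
  invisible(file)
}
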
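#' @import methods
NULL

#' TileSet: a labelled collection of RGB image tiles
#'
#' The central data container of the package: a list of uniform
#' \code{H x W x 3} arrays with intensities in \code{[0, 1]}, a benign /
#' malignant label per tile, and a magnification tag (\code{"40x"},
#' \code{"100x"}, \code{"200x"}, \code{"400x"} or \code{"synthetic"}).
#' Malignant is the positive class throughout the package.
#'
#' @slot images list of \code{H x W x 3} numeric arrays, values in [0, 1].
#' @slot labels factor with levels \code{c("benign", "malignant")}, one
#'   entry per image.
#' @slot magnification single character tag for the acquisition group.
#'
#' @seealso [generateSyntheticTiles()], [loadImageDirectory()],
#'   [stratifiedSplit()]
#' @exportClass TileSet
setClass("TileSet",
  representation(images = "list", labels = "factor",
                 magnification = "character"))

setValidity("TileSet", function(object) {
  msg <- character()
  if (length(object@images) != length(object@labels))
    msg <- c(msg, "length(images) must equal length(labels)")
  if (!identical(levels(object@labels), c("benign", "malignant")))
    msg <- c(msg, "labels must be a factor with levels benign, malignant")
  if (length(object@magnification) != 1L)
    msg <- c(msg, "magnification must be a single tag")
  bad <- vapply(object@images, function(im) {
    !(is.numeric(im) && length(dim(im)) == 3L && dim(im)[3L] == 3L &&
        all(is.finite(im)) && min(im) >= 0 && max(im) <= 1)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("%d image(s) violate the H x W x 3 in-[0,1] invariant",
                          sum(bad)))
  if (length(msg)) msg else TRUE
})

#' Construct a TileSet
#'
#' @param images list of \code{H x W x 3} arrays with values in [0, 1].
#' @param labels character or factor of \code{"benign"} / \code{"malignant"}.
#' @param magnification magnification tag; default \code{"synthetic"}.
#' @return A [TileSet-class] object.
#' @export
TileSet <- function(images, labels, magnification = "synthetic") {
  labels <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (anyNA(labels)) stop("labels must be 'benign' or 'malignant'")
  new("TileSet", images = images, labels = labels,
      magnification = magnification)
}

#' Synthetic tile generator parameters
#'
#' Parameters of the generative recipe for two-class textured RGB tiles:
#' a class-specific background colour, elliptical nucleus-like blobs
#' (Poisson count, class-specific rate; malignant tiles get denser and
#' more irregular nuclei), and additive Gaussian pixel noise, clamped to
#' [0, 1]. Defaults emulate the class imbalance of the public
#' breast-histopathology collections this package targets (roughly 70%
#' malignant prevalence).
#'
#' @slot nImages number of tiles to generate.
#' @slot malignantFraction probability in (0, 1) that a tile is malignant.
#' @slot nucleiMeanBenign,nucleiMeanMalignant Poisson rates of the
#'   nucleus count per tile for the two classes.
#' @slot radiusRange length-2 numeric, nucleus semi-axis range in pixels
#'   (>= 1).
#' @slot colorMeanBenign,colorMeanMalignant RGB background means.
#' @slot colorSpread half-width of the uniform per-tile background jitter.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot seed integer RNG seed; the generator is fully deterministic
#'   given the seed.
#' @exportClass SyntheticTileParams
setClass("SyntheticTileParams",
  representation(nImages = "integer", malignantFraction = "numeric",
                 nucleiMeanBenign = "numeric", nucleiMeanMalignant = "numeric",
                 radiusRange = "numeric",
                 colorMeanBenign = "numeric", colorMeanMalignant = "numeric",
                 colorSpread = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticTileParams", function(object) {
  msg <- character()
  if (object@nImages < 1L) msg <- c(msg, "nImages must be positive")
  if (!(object@malignantFraction > 0 && object@malignantFraction < 1))
    msg <- c(msg, "malignantFraction must lie in (0, 1)")
  if (length(object@radiusRange) != 2L || any(object@radiusRange < 1))
    msg <- c(msg, "radiusRange must be two values >= 1 pixel")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(object@colorMeanBenign) != 3L ||
      length(object@colorMeanMalignant) != 3L)
    msg <- c(msg, "class colour means must be RGB triples")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticTileParams-class
#' @param nImages,malignantFraction,nucleiMeanBenign,nucleiMeanMalignant
#'   see slot documentation.
#' @param radiusRange,colorMeanBenign,colorMeanMalignant,colorSpread,noiseSd
#'   see slot documentation.
#' @param seed integer RNG seed.
#' @return A \code{SyntheticTileParams} object.
#' @export
syntheticTileParams <- function(nImages = 400L,
                                malignantFraction = 0.686,
                                nucleiMeanBenign = 6,
                                nucleiMeanMalignant = 14,
                                radiusRange = c(2, 5),
                                colorMeanBenign = c(0.85, 0.62, 0.74),
                                colorMeanMalignant = c(0.52, 0.33, 0.58),
                                colorSpread = 0.04,
                                noiseSd = 0.02,
                                seed = 1L) {
  new("SyntheticTileParams",
      nImages = as.integer(nImages),
      malignantFraction = as.numeric(malignantFraction),
      nucleiMeanBenign = as.numeric(nucleiMeanBenign),
      nucleiMeanMalignant = as.numeric(nucleiMeanMalignant),
      radiusRange = as.numeric(radiusRange),
      colorMeanBenign = as.numeric(colorMeanBenign),
      colorMeanMalignant = as.numeric(colorMeanMalignant),
      colorSpread = as.numeric(colorSpread),
      noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Pixel-clustering transform parameters
#'
#' Configuration for the unsupervised colour-quantization transform.
#' Pixels of one tile are treated as independent RGB triples in [0, 1]
#' and clustered either by K-Means (\code{method = "KM"}, Lloyd
#' iterations from k-means++ seeding) or by flat-kernel Mean-Shift
#' (\code{method = "MS"}, bandwidth in normalized colour units).
#'
#' @slot method \code{"KM"} or \code{"MS"}.
#' @slot k cluster count (K-Means only), >= 1.
#' @slot bandwidth flat-kernel radius in normalized colour units
#'   (Mean-Shift only), > 0.
#' @slot seed integer seed for the k-means++ initialization.
#' @slot maxIter iteration cap.
#' @slot tol convergence threshold on centroid / mode movement.
#' @exportClass ClusterParams
setClass("ClusterParams",
  representation(method = "character", k = "integer", bandwidth = "numeric",
                 seed = "integer", maxIter = "integer", tol = "numeric"))

setValidity("ClusterParams", function(object) {
  msg <- character()
  if (!object@method %in% c("KM", "MS"))
    msg <- c(msg, "method must be 'KM' or 'MS'")
  if (object@method == "KM" && object@k < 1L)
    msg <- c(msg, "K must be >= 1 for K-Means")
  if (object@method == "MS" && !(object@bandwidth > 0))
    msg <- c(msg, "bandwidth must be > 0 for Mean-Shift")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be positive")
  if (!(object@tol > 0)) msg <- c(msg, "tol must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ClusterParams-class
#' @param method \code{"KM"} or \code{"MS"}.
#' @param k cluster count for K-Means (default 8).
#' @param bandwidth flat-kernel radius for Mean-Shift (default 0.2).
#' @param seed,maxIter,tol see slots.
#' @return A \code{ClusterParams} object.
#' @export
clusterParams <- function(method = c("KM", "MS"), k = 8L, bandwidth = 0.2,
                          seed = 1L, maxIter = 300L, tol = 1e-4) {
  method <- match.arg(method)
  new("ClusterParams", method = method, k = as.integer(k),
      bandwidth = as.numeric(bandwidth), seed = as.integer(seed),
      maxIter = as.integer(maxIter), tol = as.numeric(tol))
}

#' A colour-quantized tile
#'
#' Result of [quantizeImage()]: the transformed tile, the fitted palette
#' (cluster centroids or Mean-Shift modes) and the per-pixel palette
#' assignment. Every pixel of \code{pixels} equals its assigned palette
#' entry, so the number of distinct colours is at most \code{nrow(palette)}.
#'
#' @slot pixels the quantized \code{H x W x 3} array.
#' @slot palette \code{K x 3} matrix of centroid / mode colours.
#' @slot assignment integer \code{H x W} matrix of palette indices.
#' @exportClass QuantizedImage
setClass("QuantizedImage",
  representation(pixels = "array", palette = "matrix",
                 assignment = "matrix"))

setValidity("QuantizedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L) return("pixels must be H x W x 3")
  if (!identical(dim(object@assignment), d[1:2]))
    return("assignment must be an H x W index matrix")
  if (ncol(object@palette) != 3L) return("palette must be K x 3")
  rec <- array(t(object@palette)[, t(object@assignment)], dim = d[c(3, 2, 1)])
  rec <- aperm(rec, c(3, 2, 1))
  if (max(abs(rec - object@pixels)) > 1e-8)
    return("every pixel must equal its assigned palette entry")
  TRUE
})

#' Network architecture specification
#'
#' Declarative description of the three architectures: Model 1 (pure
#' CNN), Model 2 (stacked LSTM over the flattened pixel sequence) and
#' Model 3 (CNN-LSTM hybrid). For the recurrent models the flattened
#' input vector is reshaped row-major into \code{ts} time steps of
#' \code{id} features; \code{ts * id} must equal 3072 (Model 2, the
#' 32 x 32 x 3 pixel count) or 512 (Model 3, the dense bottleneck width).
#'
#' @slot modelId 1, 2 or 3.
#' @slot convMaps per-convolutional-layer feature-map counts (Models 1
#'   and 3).
#' @slot ts,id Time Steps and Input Dimension of the sequence reshape
#'   (Models 2 and 3).
#' @slot lstmUnits hidden width of the LSTM layers (default 42).
#' @slot dropoutP drop-out probability in [0, 1), default 0.25.
#' @slot denseUnits widths of the trailing dense layers.
#' @slot decision \code{"softmax"} or \code{"svm"}.
#' @slot l2Kind realization of Model 2's second recurrent block:
#'   \code{"bidirectional"} (a 42-unit bidirectional layer with summed
#'   directions, the default) or \code{"stacked"} (two further stacked
#'   42-unit layers); the two are parameter-count identical.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(modelId = "integer", convMaps = "integer", ts = "integer",
                 id = "integer", lstmUnits = "integer", dropoutP = "numeric",
                 denseUnits = "integer", decision = "character",
                 l2Kind = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@modelId %in% 1:3) msg <- c(msg, "modelId must be 1, 2 or 3")
  if (!(object@dropoutP >= 0 && object@dropoutP < 1))
    msg <- c(msg, "dropoutP must lie in [0, 1)")
  if (!object@decision %in% c("softmax", "svm"))
    msg <- c(msg, "decision must be 'softmax' or 'svm'")
  if (object@modelId == 2L && object@ts * object@id != 3072L)
    msg <- c(msg, sprintf(
      "Model 2 requires ts * id == 3072 (the 32 x 32 x 3 pixel count); got %d * %d = %d",
      object@ts, object@id, object@ts * object@id))
  if (object@modelId == 3L && object@ts * object@id != 512L)
    msg <- c(msg, sprintf(
      "Model 3 requires ts * id == 512 (the dense bottleneck width); got %d * %d = %d",
      object@ts, object@id, object@ts * object@id))
  if (!object@l2Kind %in% c("bidirectional", "stacked"))
    msg <- c(msg, "l2Kind must be 'bidirectional' or 'stacked'")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelSpec-class
#' @param modelId 1 (CNN), 2 (LSTM) or 3 (CNN-LSTM).
#' @param ts,id sequence reshape factors; required for models 2 and 3
#'   (no default is assumed).
#' @param convMaps feature-map widths; defaults: 16 per layer for
#'   Model 1, 32 per layer for Model 3.
#' @param lstmUnits,dropoutP,denseUnits,decision,l2Kind see slots.
#' @return A \code{ModelSpec} object.
#' @export
modelSpec <- function(modelId, ts = NA_integer_, id = NA_integer_,
                      convMaps = NULL, lstmUnits = 42L, dropoutP = 0.25,
                      denseUnits = NULL, decision = c("softmax", "svm"),
                      l2Kind = c("bidirectional", "stacked")) {
  modelId <- as.integer(modelId)
  decision <- match.arg(decision)
  l2Kind <- match.arg(l2Kind)
  if (modelId %in% c(2L, 3L) && (is.na(ts) || is.na(id)))
    stop("models 2 and 3 require explicit ts and id")
  if (is.null(convMaps))
    convMaps <- switch(modelId, rep(16L, 5L), integer(), rep(32L, 3L))
  if (is.null(denseUnits))
    denseUnits <- switch(modelId, integer(), 22L, c(512L, 65L))
  if (modelId == 1L) { ts <- 0L; id <- 0L }
  new("ModelSpec", modelId = modelId, convMaps = as.integer(convMaps),
      ts = as.integer(ts), id = as.integer(id),
      lstmUnits = as.integer(lstmUnits), dropoutP = as.numeric(dropoutP),
      denseUnits = as.integer(denseUnits), decision = decision,
      l2Kind = l2Kind)
}

#' Training configuration
#'
#' @slot epochs number of passes over the training set (default 500,
#'   matching the length of the learning curves the package is designed
#'   to produce; examples typically use far fewer).
#' @slot batchSize mini-batch size.
#' @slot learningRate Adam step size.
#' @slot optimizer currently \code{"adam"}.
#' @slot seed integer seed governing weight init, batching and drop-out.
#' @slot svmC soft-margin penalty C of the SVM decision head.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 seed = "integer", svmC = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (!(object@learningRate > 0)) msg <- c(msg, "learningRate must be > 0")
  if (!(object@svmC > 0)) msg <- c(msg, "svmC must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param epochs,batchSize,learningRate,optimizer,seed,svmC see slots.
#' @return A \code{TrainConfig} object.
#' @export
trainConfig <- function(epochs = 500L, batchSize = 32L, learningRate = 1e-3,
                        optimizer = "adam", seed = 1L, svmC = 1) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), optimizer = optimizer,
      seed = as.integer(seed), svmC = as.numeric(svmC))
}

#' A built network
#'
#' An ordered chain of layers (with parameter tensors) plus the spec it
#' was built from. Layers are plain lists tagged by type; the decision
#' head is the final linear layer producing two class scores
#' (benign, malignant). Use [countParameters()] for the exact trainable
#' parameter count and [predictTiles()] for inference.
#'
#' @slot layers ordered list of layer descriptions with weights.
#' @slot spec the [ModelSpec-class] the network was built from.
#' @slot inputShape integer \code{c(H, W, C)}, always \code{c(32, 32, 3)}.
#' @slot svmHead fitted SVM decision head (list) or empty list when the
#'   softmax head is in use.
#' @slot trained logical, set by [trainSoftmax()].
#' @exportClass TileNet
setClass("TileNet",
  representation(layers = "list", spec = "ModelSpec",
                 inputShape = "integer", svmHead = "list",
                 trained = "logical"))

#' Confusion counts with malignant as the positive class
#'
#' @slot tp,fp,tn,fn non-negative integer cell counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0L)) "all cells must be non-negative" else TRUE
})

#' Full metric report
#'
#' All rates are percentages in [0, 100] with malignant as the positive
#' class; sensitivity + fnRate = 100 and specificity + fpRate = 100 by
#' construction (the class-conditional rate convention). \code{mcc} is
#' the Matthews correlation coefficient in [-1, 1].
#'
#' @slot sensitivity,specificity,fpRate,fnRate,accuracy,precision,recall,fMeasure
#'   percentages.
#' @slot mcc Matthews correlation coefficient.
#' @slot precisionUndefined TRUE when tp + fp = 0 and precision was
#'   reported as 0 by convention.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(sensitivity = "numeric", specificity = "numeric",
                 fpRate = "numeric", fnRate = "numeric",
                 accuracy = "numeric", precision = "numeric",
                 recall = "numeric", fMeasure = "numeric", mcc = "numeric",
                 precisionUndefined = "logical"))
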
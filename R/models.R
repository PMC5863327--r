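#' @include AllClasses.R nn_core.R layers.R utils.R
NULL

#' Sequence shape of a flattened vector
#'
#' Factorizes a flattened feature vector of length
#' \code{vectorLength} into \code{ts} time steps of \code{id} features
#' each (row-major: step \code{t} carries elements
#' \code{(t - 1) * id + 1 ... t * id}). The product must match exactly:
#' for Model 2 the vector is the 3072-long pixel vector of a
#' 32 x 32 x 3 tile, for Model 3 the 512-wide dense bottleneck.
#'
#' @param vectorLength length of the flattened vector.
#' @param ts Time Steps.
#' @param id Input Dimension per step.
#' @return named integer \code{c(ts = ..., id = ...)}.
#' @examples
#' reshapeToSequence(3072, 24, 128)
#' @export
reshapeToSequence <- function(vectorLength, ts, id) {
  if (as.numeric(ts) * as.numeric(id) != vectorLength)
    stop("ts * id must equal ", vectorLength, ": got ts = ", ts,
         " and id = ", id, " (product ", ts * id, ")")
  c(ts = as.integer(ts), id = as.integer(id))
}

.describeShape <- function(x) paste(x, collapse = " x ")

# annotate a layer with its output description and parameter count
.annot <- function(layer, outDesc) {
  layer$outDesc <- outDesc
  layer$nParams <- sum(vapply(.layerParamNames(layer), function(nm)
    length(.layerGetParam(layer, nm)), numeric(1)))
  layer
}

.buildModel1 <- function(spec) {
  maps <- spec@convMaps
  if (length(maps) != 5L)
    stop("Model 1 needs 5 convolutional widths; got ", length(maps))
  if (maps[5L] != 16L)
    stop("Model 1's final convolutional layer has 16 feature maps")
  layers <- list()
  sh <- c(32L, 32L); cin <- 3L
  plan <- list(c("conv", 1), c("conv", 2), c("pool", 0), c("conv", 3),
               c("pool", 0), c("conv", 4), c("pool", 0), c("conv", 5))
  for (p in plan) {
    if (p[[1]] == "conv") {
      m <- maps[as.integer(p[[2]])]
      sh <- convOutputShape(sh)
      layers <- c(layers, list(.annot(.convLayer(c(sh, cin), m),
                                      .describeShape(c(sh, m)))))
      cin <- m
    } else {
      sh <- poolOutputShape(sh)
      layers <- c(layers, list(.annot(.poolLayer("max"),
                                      .describeShape(c(sh, cin)))))
    }
  }
  flat <- prod(sh) * cin
  layers <- c(layers,
              list(.annot(.flattenLayer(), as.character(flat)),
                   .annot(.dropoutLayer(spec@dropoutP), as.character(flat)),
                   .annot(.denseLayer(flat, 2L, "linear"), "2")))
  layers
}

.buildModel2 <- function(spec) {
  h <- spec@lstmUnits
  layers <- list(
    .annot(.flattenLayer(), "3072"),
    .annot(.reshapeSeqLayer(spec@ts, spec@id),
           .describeShape(c(spec@ts, spec@id))),
    .annot(.lstmLayer(spec@id, h, returnSeq = TRUE),
           .describeShape(c(spec@ts, h))))
  layers <- c(layers, if (spec@l2Kind == "bidirectional")
    list(.annot(.bilstmLayer(h, h), as.character(h)))
  else
    list(.annot(.lstmLayer(h, h, returnSeq = TRUE),
                .describeShape(c(spec@ts, h))),
         .annot(.lstmLayer(h, h, returnSeq = FALSE), as.character(h))))
  dU <- spec@denseUnits[1L]
  c(layers,
    list(.annot(.dropoutLayer(spec@dropoutP), as.character(h)),
         .annot(.denseLayer(h, dU, "relu"), as.character(dU)),
         .annot(.denseLayer(dU, 2L, "linear"), "2")))
}

.buildModel3 <- function(spec) {
  maps <- spec@convMaps
  if (length(maps) != 3L)
    stop("Model 3 needs 3 convolutional widths; got ", length(maps))
  layers <- list()
  sh <- c(32L, 32L); cin <- 3L
  for (m in maps) {
    sh <- convOutputShape(sh)
    layers <- c(layers, list(.annot(.convLayer(c(sh, cin), m),
                                    .describeShape(c(sh, m)))))
    cin <- m
  }
  sh <- poolOutputShape(sh)
  layers <- c(layers, list(.annot(.poolLayer("max"),
                                  .describeShape(c(sh, cin)))))
  flat <- prod(sh) * cin
  bott <- spec@denseUnits[1L]   # 512-wide bottleneck feeding the LSTM
  post <- spec@denseUnits[2L]   # 65-wide post-LSTM dense
  h <- spec@lstmUnits
  c(layers, list(
    .annot(.flattenLayer(), as.character(flat)),
    .annot(.denseLayer(flat, bott, "relu"), as.character(bott)),
    .annot(.reshapeSeqLayer(spec@ts, spec@id),
           .describeShape(c(spec@ts, spec@id))),
    .annot(.lstmLayer(spec@id, h, returnSeq = FALSE), as.character(h)),
    .annot(.denseLayer(h, post, "relu"), as.character(post)),
    .annot(.dropoutLayer(spec@dropoutP), as.character(post)),
    .annot(.denseLayer(post, 2L, "linear"), "2")))
}

#' Build a network from a ModelSpec
#'
#' Constructs the layer chain of the requested architecture with
#' Glorot-uniform initial weights (seeded: identical seeds give
#' identical initial weights).
#'
#' \describe{
#' \item{Model 1 (CNN)}{C1, C2 (3 x 3, same padding, ReLU, 32 x 32) ->
#'   P1 (2 x 2 max) -> C3 (16 x 16) -> P2 -> C4 (8 x 8) -> P3 ->
#'   C5 (16 maps, 4 x 4) -> flatten (256) -> drop-out (0.25) ->
#'   decision layer (2 scores). Spatial chain
#'   32, 32, 16, 16, 8, 8, 4, 4.}
#' \item{Model 2 (LSTM)}{flatten (3072) -> row-major reshape into
#'   \code{ts} steps of \code{id} features -> L-1: 42-unit LSTM
#'   returning sequences -> L-2: a second recurrent block with 42
#'   output neurons whose parameter count equals two 42-unit LSTM
#'   layers (default: bidirectional 42-unit layer with summed
#'   directions; alternative: two further stacked 42-unit layers) ->
#'   drop-out -> dense (22, ReLU) -> decision layer.}
#' \item{Model 3 (CNN-LSTM)}{C1-C3 (3 x 3, ReLU, 32 x 32) -> P1
#'   (16 x 16) -> flatten -> dense (512, ReLU) -> reshape \code{ts} x
#'   \code{id} -> 42-unit LSTM -> dense (65, ReLU) -> drop-out ->
#'   decision layer.}
#' }
#'
#' @param spec a [ModelSpec-class].
#' @param seed integer seed for weight initialization.
#' @return a [TileNet-class].
#' @examples
#' net <- buildModel(modelSpec(2, ts = 24, id = 128), seed = 1)
#' countParameters(net)  # 58280
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  layers <- withSeed(stageSeed(seed, "init"), {
    switch(spec@modelId, .buildModel1(spec), .buildModel2(spec),
           .buildModel3(spec))
  })
  new("TileNet", layers = layers, spec = spec,
      inputShape = c(32L, 32L, 3L), svmHead = list(), trained = FALSE)
}

#' @describeIn countParameters sum of element counts over every
#'   trainable tensor in the layer chain.
#' @export
setMethod("countParameters", "TileNet", function(net) {
  as.integer(sum(vapply(net@layers, function(l)
    sum(vapply(.layerParamNames(l), function(nm)
      length(.layerGetParam(l, nm)), numeric(1))), numeric(1))))
})

#' Per-layer summary of a network
#'
#' @param object a [TileNet-class].
#' @param ... unused.
#' @return data.frame with layer type, output shape and trainable
#'   parameter count per layer.
#' @export
setMethod("summary", "TileNet", function(object, ...) {
  data.frame(
    layer = vapply(object@layers, `[[`, character(1), "type"),
    output = vapply(object@layers, function(l) l$outDesc %||% "",
                    character(1)),
    parameters = vapply(object@layers, function(l)
      as.integer(l$nParams %||% 0L), integer(1)))
})

setMethod("show", "TileNet", function(object) {
  cat(sprintf("TileNet: Model %d (%s head)%s\n", object@spec@modelId,
              object@spec@decision,
              if (object@trained) ", trained" else ""))
  print(summary(object))
  cat("total trainable parameters:", countParameters(object), "\n")
})

# forward pass through the full chain
# x: array (H, W, C, B); returns scores (B x 2), per-layer caches and
# the penultimate features (input of the decision layer)
.netForward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net@layers))
  penult <- NULL
  for (i in seq_along(net@layers)) {
    if (i == length(net@layers)) penult <- x
    r <- .layerForward(net@layers[[i]], x, training)
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(scores = x, caches = caches, penultimate = penult)
}

# backward pass; dscores (B x 2) -> list of per-layer gradient lists
.netBackward <- function(net, caches, dscores) {
  grads <- vector("list", length(net@layers))
  d <- dscores
  for (i in rev(seq_along(net@layers))) {
    r <- .layerBackward(net@layers[[i]], d, caches[[i]])
    grads[i] <- list(r$grads)
    d <- r$dx
  }
  grads
}

# stack the images of a TileSet (or list) into an (H, W, C, B) tensor
.tilesToArray <- function(x) {
  images <- if (is(x, "TileSet")) tileImages(x) else x
  d <- dim(images[[1L]])
  array(unlist(images, use.names = FALSE), c(d, length(images)))
}
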
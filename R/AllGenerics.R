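#' @include AllClasses.R
NULL

#' Number of tiles in a TileSet
#' @param x a [TileSet-class].
#' @return integer count.
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' Tile labels
#' @param x a [TileSet-class].
#' @return factor of benign / malignant labels.
#' @export
setGeneric("tileLabels", function(x) standardGeneric("tileLabels"))

#' Tile images
#' @param x a [TileSet-class].
#' @return list of \code{H x W x 3} arrays.
#' @export
setGeneric("tileImages", function(x) standardGeneric("tileImages"))

#' Magnification tag
#' @param x a [TileSet-class].
#' @return single character tag.
#' @export
setGeneric("magnification", function(x) standardGeneric("magnification"))

#' Apply the clustering transform to every tile
#' @param x a [TileSet-class].
#' @param params a [ClusterParams-class].
#' @return a new [TileSet-class] of quantized tiles.
#' @export
setGeneric("quantizeTiles", function(x, params) standardGeneric("quantizeTiles"))

#' Exact trainable parameter count of a network
#'
#' Sums the element counts of every trainable tensor in the network;
#' by construction this equals the analytic sum of the per-layer count
#' formulas ([lstmParamCount()], [denseParamCount()]).
#'
#' @param net a [TileNet-class].
#' @return integer parameter count.
#' @export
setGeneric("countParameters", function(net) standardGeneric("countParameters"))

setMethod("nTiles", "TileSet", function(x) length(x@images))
setMethod("tileLabels", "TileSet", function(x) x@labels)
setMethod("tileImages", "TileSet", function(x) x@images)
setMethod("magnification", "TileSet", function(x) x@magnification)

#' Subset a TileSet
#' @param x a [TileSet-class].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @return a [TileSet-class] with the selected tiles.
#' @export
setMethod("[", "TileSet", function(x, i, j, ..., drop = FALSE) {
  new("TileSet", images = x@images[i], labels = x@labels[i],
      magnification = x@magnification)
})

setMethod("show", "TileSet", function(object) {
  tab <- table(object@labels)
  d <- if (length(object@images)) dim(object@images[[1L]]) else c(0L, 0L, 0L)
  cat(sprintf("TileSet: %d tiles (%d x %d x %d), %s\n",
              length(object@images), d[1], d[2], d[3],
              object@magnification))
  cat(sprintf("  benign: %d  malignant: %d\n", tab[["benign"]],
              tab[["malignant"]]))
})

setMethod("show", "ClusterParams", function(object) {
  if (object@method == "KM")
    cat(sprintf("ClusterParams: K-Means, K = %d, seed = %d\n",
                object@k, object@seed))
  else
    cat(sprintf("ClusterParams: Mean-Shift, bandwidth = %g\n",
                object@bandwidth))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (malignant positive): TP=%d FP=%d TN=%d FN=%d\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (%, malignant positive)\n")
  cat(sprintf("  sensitivity %.2f  specificity %.2f  FP %.2f  FN %.2f\n",
              object@sensitivity, object@specificity, object@fpRate,
              object@fnRate))
  cat(sprintf("  accuracy %.2f  precision %.2f  F-measure %.2f  MCC %.4f\n",
              object@accuracy, object@precision, object@fMeasure,
              object@mcc))
  if (object@precisionUndefined)
    cat("  note: no positive predictions; precision reported as 0\n")
})

#' Coerce a MetricReport to a one-row data.frame
#' @param x a [MetricReport-class].
#' @param ... unused.
#' @return one-row data.frame with all metric columns.
#' @export
setMethod("as.data.frame", "MetricReport", function(x, ...) {
  data.frame(sensitivity_pct = x@sensitivity, specificity_pct = x@specificity,
             fp_rate_pct = x@fpRate, fn_rate_pct = x@fnRate,
             accuracy_pct = x@accuracy, precision_pct = x@precision,
             recall_pct = x@recall, f_measure_pct = x@fMeasure,
             mcc = x@mcc, precision_undefined = x@precisionUndefined)
})
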
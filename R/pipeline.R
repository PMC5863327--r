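#' @include AllClasses.R io.R synthetic.R clustering.R train.R metrics.R
NULL

#' Experiment configuration
#'
#' Bundles one complete run of the pipeline: exactly one data source
#' (a synthetic generator spec or an image directory), an optional
#' clustering transform (\code{NULL} = the original-image "OI" arm),
#' the architecture, the training configuration, the split fraction
#' and an output directory. A single global \code{seed} fans out to
#' deterministic per-stage seeds (generator, clustering, split, weight
#' init, batching), so one number reproduces the whole run.
#'
#' @slot synthetic a [SyntheticTileParams-class], or NULL.
#' @slot dataDir image directory path, or NA.
#' @slot layout,magnificationSel directory layout options for
#'   [loadImageDirectory()].
#' @slot cluster a [ClusterParams-class] or NULL (OI arm).
#' @slot model a [ModelSpec-class].
#' @slot train a [TrainConfig-class].
#' @slot testFraction held-out proportion (default 0.30).
#' @slot outDir artifact directory.
#' @slot seed global integer seed.
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(synthetic = "ANY", dataDir = "character",
                 layout = "character", magnificationSel = "character",
                 cluster = "ANY", model = "ModelSpec",
                 train = "TrainConfig", testFraction = "numeric",
                 outDir = "character", seed = "integer"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  hasSynth <- !is.null(object@synthetic)
  hasDir <- !is.na(object@dataDir)
  if (hasSynth == hasDir)
    msg <- c(msg, "exactly one data source (synthetic or dataDir) required")
  if (hasDir && !dir.exists(object@dataDir))
    msg <- c(msg, paste0("dataDir does not exist: ", object@dataDir))
  if (!is.null(object@cluster) && !is(object@cluster, "ClusterParams"))
    msg <- c(msg, "cluster must be NULL or a ClusterParams")
  if (!(object@testFraction > 0 && object@testFraction < 1))
    msg <- c(msg, "testFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname ExperimentConfig-class
#' @param synthetic,dataDir,layout,magnification,cluster,model,train see
#'   slots.
#' @param testFraction,outDir,seed see slots.
#' @return an \code{ExperimentConfig} object.
#' @export
experimentConfig <- function(synthetic = NULL, dataDir = NULL,
                             layout = "flat", magnification = NULL,
                             cluster = NULL, model,
                             train = trainConfig(epochs = 50L),
                             testFraction = 0.3,
                             outDir = tempfile("deepTiles_run_"),
                             seed = 1L) {
  new("ExperimentConfig", synthetic = synthetic,
      dataDir = dataDir %||% NA_character_, layout = layout,
      magnificationSel = magnification %||% NA_character_,
      cluster = cluster, model = model, train = train,
      testFraction = as.numeric(testFraction), outDir = outDir,
      seed = as.integer(seed))
}

# run one pipeline stage with structured logging; errors carry the
# stage name
.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

.configAsList <- function(cfg) {
  list(
    seed = cfg@seed,
    data = if (!is.null(cfg@synthetic)) list(
      source = "synthetic", nImages = cfg@synthetic@nImages,
      malignantFraction = cfg@synthetic@malignantFraction,
      noiseSd = cfg@synthetic@noiseSd)
    else list(source = "directory", dataDir = cfg@dataDir,
              layout = cfg@layout,
              magnification = cfg@magnificationSel),
    cluster = if (is.null(cfg@cluster)) list(method = "OI")
      else list(method = cfg@cluster@method, k = cfg@cluster@k,
                bandwidth = cfg@cluster@bandwidth),
    model = list(modelId = cfg@model@modelId, ts = cfg@model@ts,
                 id = cfg@model@id, decision = cfg@model@decision,
                 dropoutP = cfg@model@dropoutP),
    train = list(epochs = cfg@train@epochs, batchSize = cfg@train@batchSize,
                 learningRate = cfg@train@learningRate,
                 svmC = cfg@train@svmC),
    testFraction = cfg@testFraction)
}

#' Run one experiment end-to-end
#'
#' Load or generate the tiles, optionally apply the clustering
#' transform, split, build, train, optionally fit the SVM head,
#' evaluate on the held-out test part, and persist the artifacts:
#' \code{metrics.csv} (one row, carrying the config hash),
#' \code{history.csv}, \code{curves.png}, \code{model.rds} and a
#' machine-readable \code{manifest.json} (config + seed + versions).
#' Re-running an identical config reproduces all numeric outputs
#' bit-for-bit on one CPU thread.
#'
#' @param cfg an [ExperimentConfig-class].
#' @return invisibly, a list with \code{report}
#'   ([MetricReport-class]), \code{counts}, \code{history},
#'   \code{net}, \code{manifest} and \code{row} (the one-row metrics
#'   data.frame).
#' @export
runExperiment <- function(cfg) {
  stopifnot(is(cfg, "ExperimentConfig"))
  validObject(cfg)
  dir.create(cfg@outDir, showWarnings = FALSE, recursive = TRUE)

  ds <- .stage("load", {
    if (!is.null(cfg@synthetic)) {
      p <- cfg@synthetic
      p@seed <- stageSeed(cfg@seed, "generate")
      generateSyntheticTiles(p)
    } else {
      loadImageDirectory(cfg@dataDir, cfg@layout,
                         if (is.na(cfg@magnificationSel)) NULL
                         else cfg@magnificationSel)
    }
  })

  if (!is.null(cfg@cluster)) {
    ds <- .stage("quantize", {
      cl <- cfg@cluster
      cl@seed <- stageSeed(cfg@seed, "cluster")
      quantizeTiles(ds, cl)
    })
  }

  parts <- .stage("split",
    stratifiedSplit(ds, cfg@testFraction, stageSeed(cfg@seed, "split")))

  net <- .stage("build", buildModel(cfg@model, seed = cfg@seed))

  tr <- .stage("train", {
    tc <- cfg@train
    tc@seed <- cfg@seed
    trainSoftmax(net, parts$train, parts$test, tc)
  })
  net <- tr$net

  if (cfg@model@decision == "svm")
    net <- .stage("svm-head", fitSvmHead(net, parts$train, cfg@train@svmC))

  out <- .stage("evaluate", {
    pred <- predictTiles(net, parts$test)
    cc <- confusionCounts(tileLabels(parts$test), pred)
    list(counts = cc, report = metricReport(cc))
  })

  manifest <- c(.configAsList(cfg),
                list(package = "deepTiles",
                     package_version =
                       as.character(utils::packageVersion("deepTiles")),
                     r_version = as.character(getRversion())))
  hash <- configHash(.configAsList(cfg))
  row <- cbind(
    data.frame(dataset = magnification(ds),
               cluster = if (is.null(cfg@cluster)) "OI"
                         else cfg@cluster@method,
               model = cfg@model@modelId,
               decision = cfg@model@decision),
    as.data.frame(out$report),
    data.frame(config_hash = hash))

  .stage("persist", {
    utils::write.csv(row, file.path(cfg@outDir, "metrics.csv"),
                     row.names = FALSE)
    exportHistory(tr$history, file.path(cfg@outDir, "history.csv"))
    if (nrow(tr$history))
      plotHistory(tr$history, file.path(cfg@outDir, "curves.png"))
    saveRDS(net, file.path(cfg@outDir, "model.rds"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(cfg@outDir, "manifest.json"))
    NULL
  })

  invisible(list(report = out$report, counts = out$counts,
                 history = tr$history, net = net, manifest = manifest,
                 row = row))
}

#' Run the full experimental grid
#'
#' Executes every combination of cluster arm (\code{OI} = original
#' images, \code{KM}, \code{MS}), model (1-3) and decision layer
#' (softmax, svm) on one dataset: 18 result rows with the default
#' axes. For each cluster arm and model the network is trained once in
#' the softmax regime; the SVM row re-uses its features (the
#' two-stage decision-head design).
#'
#' @param cfg an [ExperimentConfig-class]; its \code{model} slot
#'   supplies defaults (drop-out, decision is ignored).
#' @param clusters subset of \code{c("OI", "KM", "MS")}.
#' @param models subset of \code{1:3}.
#' @param decisions subset of \code{c("softmax", "svm")}.
#' @param tsId2,tsId3 explicit \code{c(ts, id)} for models 2 and 3
#'   (required when those models are in \code{models}; no default is
#'   assumed).
#' @param k,bandwidth clustering parameters of the KM / MS arms.
#' @return data.frame with one metrics row per combination, also
#'   written to \code{grid_metrics.csv} under \code{cfg@outDir}.
#' @export
runGrid <- function(cfg, clusters = c("OI", "KM", "MS"), models = 1:3,
                    decisions = c("softmax", "svm"),
                    tsId2 = NULL, tsId3 = NULL, k = 8L, bandwidth = 0.2) {
  stopifnot(is(cfg, "ExperimentConfig"))
  if (2L %in% models && is.null(tsId2))
    stop("tsId2 = c(ts, id) is required when model 2 is in the grid")
  if (3L %in% models && is.null(tsId3))
    stop("tsId3 = c(ts, id) is required when model 3 is in the grid")
  raw <- .stage("load", {
    if (!is.null(cfg@synthetic)) {
      p <- cfg@synthetic
      p@seed <- stageSeed(cfg@seed, "generate")
      generateSyntheticTiles(p)
    } else {
      loadImageDirectory(cfg@dataDir, cfg@layout,
                         if (is.na(cfg@magnificationSel)) NULL
                         else cfg@magnificationSel)
    }
  })
  rows <- list()
  for (cl in clusters) {
    clParams <- switch(cl, OI = NULL,
                       KM = clusterParams("KM", k = k,
                                          seed = stageSeed(cfg@seed,
                                                           "cluster")),
                       MS = clusterParams("MS", bandwidth = bandwidth))
    ds <- if (is.null(clParams)) raw
          else .stage(paste0("quantize-", cl), quantizeTiles(raw, clParams))
    parts <- stratifiedSplit(ds, cfg@testFraction,
                             stageSeed(cfg@seed, "split"))
    for (m in models) {
      spec <- switch(m,
        modelSpec(1L, dropoutP = cfg@model@dropoutP),
        modelSpec(2L, ts = tsId2[1L], id = tsId2[2L],
                  dropoutP = cfg@model@dropoutP),
        modelSpec(3L, ts = tsId3[1L], id = tsId3[2L],
                  dropoutP = cfg@model@dropoutP))
      tc <- cfg@train
      tc@seed <- cfg@seed
      tr <- .stage(sprintf("train-%s-model%d", cl, m),
                   trainSoftmax(buildModel(spec, seed = cfg@seed),
                                parts$train, parts$test, tc))
      netSvm <- NULL
      for (dec in decisions) {
        net <- if (dec == "softmax") tr$net
               else netSvm <- fitSvmHead(tr$net, parts$train,
                                         cfg@train@svmC)
        pred <- predictTiles(net, parts$test)
        rep <- metricReport(confusionCounts(tileLabels(parts$test), pred))
        sub <- cfg
        sub@cluster <- clParams
        sp2 <- spec; sp2@decision <- dec
        sub@model <- sp2
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(dataset = magnification(ds), cluster = cl,
                     model = m, decision = dec),
          as.data.frame(rep),
          data.frame(config_hash = configHash(.configAsList(sub))))
      }
    }
  }
  out <- do.call(rbind, rows)
  dir.create(cfg@outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(cfg@outDir, "grid_metrics.csv"),
                   row.names = FALSE)
  out
}

#' Parameter sweeps along the paper-style axes
#'
#' Runs one experiment per value of the chosen axis and aggregates the
#' metric rows: \code{K} sweeps the K-Means cluster count (default
#' 8, 16, 24), \code{BW} the Mean-Shift bandwidth (default 0.2, 0.4,
#' 0.6), and \code{TS_ID} the Model-2 sequence factorizations (default
#' the six pairs (24,128), (32,96), (48,64), (64,48), (96,32),
#' (128,24)); the \code{TS_ID} axis also emits the analytic trainable
#' parameter count per pair.
#'
#' @param cfg an [ExperimentConfig-class] template.
#' @param axis \code{"K"}, \code{"BW"} or \code{"TS_ID"}.
#' @param values axis values; NULL picks the defaults above. For
#'   \code{TS_ID}, a list of \code{c(ts, id)} pairs.
#' @return data.frame of metric rows (one per value), written to
#'   \code{sweep_<axis>.csv} under \code{cfg@outDir}.
#' @export
sweepExperiments <- function(cfg, axis = c("K", "BW", "TS_ID"),
                             values = NULL) {
  axis <- match.arg(axis)
  if (is.null(values))
    values <- switch(axis,
      K = c(8L, 16L, 24L),
      BW = c(0.2, 0.4, 0.6),
      TS_ID = list(c(24L, 128L), c(32L, 96L), c(48L, 64L), c(64L, 48L),
                   c(96L, 32L), c(128L, 24L)))
  if (length(values) == 0L) stop("empty sweep axis")
  rows <- list()
  for (v in values) {
    sub <- cfg
    tag <- NULL
    if (axis == "K") {
      sub@cluster <- clusterParams("KM", k = v)
      tag <- data.frame(K = v)
    } else if (axis == "BW") {
      sub@cluster <- clusterParams("MS", bandwidth = v)
      tag <- data.frame(BW = v)
    } else {
      sub@model <- modelSpec(2L, ts = v[1L], id = v[2L],
                             decision = cfg@model@decision,
                             dropoutP = cfg@model@dropoutP)
      tag <- data.frame(TS = v[1L], ID = v[2L],
                        parameters = countParameters(
                          buildModel(sub@model, seed = sub@seed)))
    }
    sub@outDir <- file.path(cfg@outDir,
                            paste0(axis, "_", paste(unlist(v),
                                                    collapse = "_")))
    res <- runExperiment(sub)
    rows[[length(rows) + 1L]] <- cbind(tag, res$row)
  }
  out <- do.call(rbind, rows)
  dir.create(cfg@outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(cfg@outDir,
                                  paste0("sweep_", axis, ".csv")),
                   row.names = FALSE)
  out
}
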
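# Independent oracles and small fixture builders used across the suite.

# pixel-mean threshold classifier: the separability oracle for the
# noise-free synthetic data (threshold at the midpoint of class means)
thresholdOracle <- function(ds) {
  m <- vapply(tileImages(ds), mean, numeric(1))
  lab <- tileLabels(ds)
  thr <- (mean(m[lab == "benign"]) + mean(m[lab == "malignant"])) / 2
  factor(ifelse(m < thr, "malignant", "benign"),
         levels = c("benign", "malignant"))
}

# brute-force metric formulas, written independently of metricReport
bruteMetrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(sens = sens, spec = spec, acc = 100 * (tp + tn) / n, prec = prec,
       f = f, mcc = mcc)
}

# tiny labelled TileSet built from constant-colour tiles
constantTileSet <- function(labels, shade = NULL) {
  n <- length(labels)
  if (is.null(shade)) shade <- seq(0.2, 0.8, length.out = n)
  images <- lapply(shade, function(s) array(s, c(32L, 32L, 3L)))
  TileSet(images, labels)
}

# direct grid minimization of the soft-margin objective (no intercept)
svmGridOracle <- function(X, y, C, grid = seq(-2, 2, by = 0.05)) {
  best <- Inf; bestW <- NULL
  for (w1 in grid) for (w2 in grid) {
    obj <- svmObjective(c(w1, w2), X, y, C)
    if (obj < best) { best <- obj; bestW <- c(w1, w2) }
  }
  list(W = bestW, objective = best)
}
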
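#' @include AllClasses.R utils.R
NULL

# evaluate expr under a private RNG state, restoring the caller's
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# paint one elliptical nucleus-like blob onto a tile, in place
.paintNucleus <- function(img, cx, cy, a, b, theta, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  X <- matrix(seq_len(H), H, W)
  Y <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- X - cx; dy <- Y - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

.synthTile <- function(malignant, p) {
  bg <- (if (malignant) p@colorMeanMalignant else p@colorMeanBenign) +
    p@colorSpread * runif(3, -1, 1)
  img <- array(rep(clamp01(bg), each = 32L * 32L), dim = c(32L, 32L, 3L))
  rate <- if (malignant) p@nucleiMeanMalignant else p@nucleiMeanBenign
  nNuc <- stats::rpois(1L, rate)
  for (i in seq_len(nNuc)) {
    cx <- runif(1, 1, 32); cy <- runif(1, 1, 32)
    a <- runif(1, p@radiusRange[1L], p@radiusRange[2L])
    # malignant nuclei are more irregular: stronger elongation spread
    ratio <- if (malignant) runif(1, 0.30, 0.90) else runif(1, 0.75, 1.00)
    b <- max(1, a * ratio)
    theta <- runif(1, 0, pi)
    col <- clamp01(c(0.30, 0.18, 0.45) + runif(3, -0.05, 0.05))
    img <- .paintNucleus(img, cx, cy, a, b, theta, col)
  }
  if (p@noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, p@noiseSd)
  clamp01(img)
}

#' Generate a synthetic two-class tile dataset
#'
#' Draws \code{nImages} 32 x 32 x 3 tiles from a documented generative
#' recipe: each tile gets a class-specific background colour (uniform
#' per-tile jitter), a Poisson number of elliptical nucleus-like blobs
#' (malignant tiles have a higher rate and more elongated, irregular
#' blobs), and additive Gaussian pixel noise, all clamped to [0, 1].
#' Labels are Bernoulli draws with probability
#' \code{malignantFraction}; the defaults emulate the roughly 70\%
#' malignant prevalence of public breast-histopathology collections.
#' The generator is fully deterministic: identical parameters (including
#' the seed) yield bitwise-identical datasets, and the caller's RNG
#' state is left untouched.
#'
#' @param params a [SyntheticTileParams-class] (see
#'   [syntheticTileParams()]).
#' @return a [TileSet-class] with magnification tag \code{"synthetic"}.
#' @examples
#' ds <- generateSyntheticTiles(syntheticTileParams(nImages = 20, seed = 1))
#' table(tileLabels(ds))
#' @export
generateSyntheticTiles <- function(params) {
  stopifnot(is(params, "SyntheticTileParams"))
  validObject(params)
  withSeed(params@seed, {
    n <- params@nImages
    lab <- stats::rbinom(n, 1L, params@malignantFraction)
    if (length(unique(lab)) < 2L && n >= 2L) {
      warning("degenerate label draw; flipping one label so both classes ",
              "are present")
      lab[n] <- 1L - lab[n]
    }
    images <- lapply(seq_len(n), function(i) .synthTile(lab[i] == 1L, params))
    TileSet(images, ifelse(lab == 1L, "malignant", "benign"), "synthetic")
  })
}

#' Write a TileSet as a directory of PNGs plus a CSV manifest
#'
#' @param x a [TileSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame
#'   (\code{filename, label, magnification_tag}).
#' @seealso [readTileSet()]
#' @export
writeTileSet <- function(x, dir) {
  stopifnot(is(x, "TileSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("tile_%04d.png", seq_len(nTiles(x)))
  for (i in seq_len(nTiles(x))) {
    im <- EBImage::Image(aperm(x@images[[i]], c(2, 1, 3)),
                         colormode = "Color")
    EBImage::writeImage(im, file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files,
                         label = as.character(x@labels),
                         magnification_tag = x@magnification)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a TileSet written by [writeTileSet()]
#'
#' @param dir directory containing PNGs and a \code{manifest.csv}.
#' @return a [TileSet-class].
#' @export
readTileSet <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  images <- lapply(file.path(dir, manifest$filename), .readTileFile)
  TileSet(images, manifest$label,
          unique(manifest$magnification_tag)[1L])
}
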
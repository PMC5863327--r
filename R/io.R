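#' @include AllClasses.R utils.R
NULL

.IMG_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")

# read one image file -> 32 x 32 x 3 array in [0,1]
# (bilinear resize, aspect ratio not preserved; grayscale replicated to
# three channels; alpha dropped)
.readTileFile <- function(path) {
  im <- EBImage::readImage(path)
  im <- EBImage::resize(im, w = 32L, h = 32L)   # bilinear by default
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  clamp01(aperm(a, c(2, 1, 3)))   # EBImage stores x (width) first
}

.listImages <- function(dir) {
  list.files(dir, pattern = paste0("\\.(", paste(.IMG_EXT, collapse = "|"),
                                   ")$"),
             ignore.case = TRUE, full.names = TRUE, recursive = TRUE)
}

#' Load a labelled image directory as a TileSet
#'
#' Reads PNG/JPEG/TIFF files, resizes every image to 32 x 32 x 3 by
#' bilinear interpolation (aspect ratio not preserved: e.g. a
#' 760 x 460 source maps directly onto 32 x 32) and scales intensities
#' to [0, 1]. Labels come from the directory structure.
#'
#' Layouts:
#' \describe{
#'   \item{\code{flat}}{\code{root/benign/*.png},
#'     \code{root/malignant/*.png} (nested subfolders allowed).}
#'   \item{\code{breakhis}}{\code{root/<benign|malignant>/<40x|100x|200x|400x>/...},
#'     the magnification-grouped layout of public breast-histopathology
#'     collections; use \code{magnification} to select one group.}
#' }
#'
#' Unreadable files are skipped with a per-file warning and a final
#' count; an empty class is an error.
#'
#' @param root directory to read.
#' @param layout \code{"flat"} or \code{"breakhis"}.
#' @param magnification for \code{breakhis}: one of \code{"40x"},
#'   \code{"100x"}, \code{"200x"}, \code{"400x"}, or NULL for all groups.
#' @return a [TileSet-class].
#' @export
loadImageDirectory <- function(root, layout = c("flat", "breakhis"),
                               magnification = NULL) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("directory does not exist: ", root)
  images <- list(); labels <- character(); nbad <- 0L
  for (cls in c("benign", "malignant")) {
    sub <- file.path(root, cls)
    if (layout == "breakhis" && !is.null(magnification))
      sub <- file.path(sub, magnification)
    files <- if (dir.exists(sub)) .listImages(sub) else character()
    if (!length(files))
      stop("no readable images for class '", cls, "' under ", sub)
    for (f in files) {
      a <- tryCatch(.readTileFile(f), error = function(e) {
        warning("skipping unreadable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(a)) { nbad <- nbad + 1L; next }
      images[[length(images) + 1L]] <- a
      labels <- c(labels, cls)
    }
  }
  if (nbad > 0L) message(nbad, " file(s) skipped as unreadable")
  tag <- if (layout == "breakhis") magnification %||% "mixed" else "flat"
  TileSet(images, labels, tag)
}

#' Stratified train/test split
#'
#' Splits a [TileSet-class] into disjoint, exhaustive train and test
#' parts, preserving the class proportions to within one image
#' (per class, \code{round(n_class * testFraction)} images go to the
#' test part, clipped so both parts keep at least one image of each
#' class). Seeded and reproducible.
#'
#' @param ds a [TileSet-class]; both classes need at least 2 members.
#' @param testFraction proportion in (0, 1); default 0.30.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}
#'   ([TileSet-class] each).
#' @export
stratifiedSplit <- function(ds, testFraction = 0.3, seed = 1L) {
  stopifnot(is(ds, "TileSet"))
  if (!(testFraction > 0 && testFraction < 1))
    stop("testFraction must lie in (0, 1)")
  lab <- tileLabels(ds)
  counts <- table(lab)
  if (any(counts < 2L))
    stop("each class needs at least 2 members to stratify")
  testIdx <- withSeed(seed, {
    unlist(lapply(levels(lab), function(cl) {
      idx <- which(lab == cl)
      nTest <- min(max(round(length(idx) * testFraction), 1L),
                   length(idx) - 1L)
      sample(idx, nTest)
    }))
  })
  testIdx <- sort(testIdx)
  list(train = ds[setdiff(seq_along(lab), testIdx)], test = ds[testIdx])
}
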
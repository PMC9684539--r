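## Preprocessing: class filtering, stratified folds, resizing, augmentation.

#' Preprocessing configuration
#'
#' Default target geometry is 256 px wide by 116 px high with intensities
#' normalised into (0, 1) by a global /255 on 8-bit input.
#'
#' @param width,height target size in px.
#' @param valueRange numeric (low, high).
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(width = 256L, height = 116L,
                             valueRange = c(0, 1)) {
  new("PreprocessConfig", width = as.integer(width),
      height = as.integer(height), value_range = as.numeric(valueRange))
}

#' Remove under-sampled classes
#'
#' Classes (at the manifest's working level) with fewer than \code{minCount}
#' records are discarded to prevent overfitting on a handful of specimens;
#' the class index is rebuilt over the survivors.  Idempotent.
#'
#' @param manifest a [WingManifest-class].
#' @param minCount minimum class size to retain (default 10: classes with
#'   fewer than 10 samples are dropped).
#' @return a filtered [WingManifest-class] (possibly empty).
#' @export
filterUndersampled <- function(manifest, minCount = 10L) {
  stopifnot(is(manifest, "WingManifest"), minCount >= 1)
  cls <- manifestClasses(manifest)
  keep <- cls %in% names(which(table(cls) >= minCount))
  wingManifest(manifest@records[keep, , drop = FALSE], level = manifest@level)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class with its own substream of the master seed and deals
#' records round-robin into folds, starting at an offset derived from the
#' class index, so folds are an exact partition with per-class sizes
#' differing by at most one, and the assignment is a pure function of
#' (manifest, k, seed).
#'
#' @param manifest a [WingManifest-class].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a [FoldAssignment-class].
#' @export
makeFolds <- function(manifest, k = 5L, seed = 0L) {
  stopifnot(is(manifest, "WingManifest"))
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  recs <- manifest@records
  if (nrow(recs) < k) stop("k exceeds the number of records")
  cls <- manifestClasses(manifest)
  assign <- integer(nrow(recs))
  names(assign) <- recs$id
  for (ci in seq_along(sort(unique(cls)))) {
    cname <- sort(unique(cls))[ci]
    ridx <- which(cls == cname)
    perm <- withSeed(recordSeed(seed, ci), sample.int(length(ridx)))
    offset <- (ci - 1L) %% k
    folds <- (offset + seq_along(ridx) - 1L) %% k
    assign[ridx[perm]] <- folds
  }
  new("FoldAssignment", k = k, assignment = assign)
}

#' @describeIn makeFolds fold vector accessor (named by record id).
#' @param object a \code{FoldAssignment}.
#' @export
foldAssignment <- function(object) object@assignment

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d records in k = %d folds (sizes: %s)\n",
              length(object@assignment), object@k,
              paste(tabulate(object@assignment + 1L, object@k),
                    collapse = ", ")))
})

#' Write / read a fold assignment as CSV (\code{id,fold})
#'
#' @param folds a [FoldAssignment-class].
#' @param file CSV path.
#' @export
writeFolds <- function(folds, file) {
  utils::write.csv(data.frame(id = names(folds@assignment),
                              fold = unname(folds@assignment)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeFolds
#' @export
readFolds <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  a <- as.integer(df$fold)
  names(a) <- df$id
  new("FoldAssignment", k = max(a) + 1L, assignment = a)
}

#' Resize and normalise an image
#'
#' Bilinear resize to the configured geometry (default 256 wide x 116 high)
#' and global division by the input's nominal maximum (255 for 8-bit, 65535
#' for 16-bit), mapping intensities into the configured range.  An input
#' already at the target size is only rescaled in value, never resampled.
#'
#' @param image H x W x 3 array of raw intensities.
#' @param config a [PreprocessConfig-class].
#' @param maxValue nominal full-scale input value (default 255).
#' @return array (height, width, 3) with values in the configured range.
#' @export
resizeNormalize <- function(image, config = preprocessConfig(),
                            maxValue = 255) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("input must be an RGB (H x W x 3) array")
  img <- image / maxValue
  img <- .clip01(img)
  img <- .clip01(.resizeBilinear(img, config@height, config@width))
  lo <- config@value_range[1]; hi <- config@value_range[2]
  lo + img * (hi - lo)
}

#' Training-time augmentation
#'
#' Random horizontal/vertical flips, rotation uniform in
#' \[-maxRotation, +maxRotation\] degrees and isotropic zoom uniform in
#' \code{zoomRange}, in that order.  Deterministic under a fixed seed; with
#' all parts disabled it is the identity.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param flipH,flipV allow the corresponding flip (drawn with probability
#'   1/2 when allowed).
#' @param maxRotation degrees (default 15).
#' @param zoomRange numeric (lo, hi), default c(0.9, 1.1).
#' @param seed integer seed.
#' @return augmented image, same shape.
#' @export
augmentImage <- function(image, flipH = TRUE, flipV = TRUE, maxRotation = 15,
                         zoomRange = c(0.9, 1.1), seed = 0L) {
  if (zoomRange[1] > zoomRange[2]) stop("zoom range must have lo <= hi")
  withSeed(seed, {
    if (flipH && stats::runif(1) < 0.5) image <- .flipH(image)
    if (flipV && stats::runif(1) < 0.5) image <- .flipV(image)
    ang <- if (maxRotation > 0) stats::runif(1, -maxRotation, maxRotation) else 0
    zm <- if (diff(zoomRange) > 0 || zoomRange[1] != 1)
      stats::runif(1, zoomRange[1], zoomRange[2]) else 1
    if (ang != 0 || zm != 1)
      image <- .warpRotateZoom(image, ang, zm, fill = .WIP_BACKGROUND)
    image
  })
}
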
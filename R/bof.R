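## Classical baseline: local keypoint descriptors, a visual-word dictionary,
## bag-of-features histograms and a polynomial-kernel SVM.
##
## The descriptor stage is a rotation-robust gradient descriptor (Harris
## keypoints, orientation-normalised 4x4 grid of 8-bin gradient histograms,
## 128-d) behind the same contract a SURF extractor would satisfy: local,
## fixed dimension, empty on structureless images.

.DESCRIPTOR_DIM <- 128L
.PATCH_HALF <- 8L

#' Extract local keypoint descriptors
#'
#' Detects Harris corners on the luminance channel and computes an
#' orientation-normalised gradient-histogram descriptor (4 x 4 spatial cells
#' x 8 orientation bins) around each.  Deterministic; a constant image
#' yields no keypoints.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param maxKeypoints cap on returned keypoints (strongest first).
#' @return matrix (n x 128) of descriptors with keypoint coordinates in
#'   attribute \code{"coords"} (columns x, y); zero rows when no structure.
#' @export
extractDescriptors <- function(image, maxKeypoints = 200L) {
  g <- .rgb2gray(image)
  H <- nrow(g); W <- ncol(g)
  empty <- matrix(numeric(), 0, .DESCRIPTOR_DIM)
  attr(empty, "coords") <- matrix(numeric(), 0, 2)
  m <- .PATCH_HALF
  if (H < 2 * m + 3 || W < 2 * m + 3) return(empty)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  Ixx <- .blurMatrix(gx * gx, 1.5)
  Iyy <- .blurMatrix(gy * gy, 1.5)
  Ixy <- .blurMatrix(gx * gy, 1.5)
  R <- (Ixx * Iyy - Ixy^2) - 0.04 * (Ixx + Iyy)^2
  thr <- 0.01 * max(R)
  if (!is.finite(thr) || max(R) <= 1e-12) return(empty)
  ## 3x3 local maxima above threshold, away from the border
  isMax <- R >= thr
  sh <- function(M, dy, dx) {
    out <- matrix(-Inf, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- M[ys - dy, xs - dx]
    out
  }
  for (dy in -1:1) for (dx in -1:1)
    if (dy || dx) isMax <- isMax & (R >= sh(R, dy, dx))
  isMax[c(1:(m + 1), (H - m):H), ] <- FALSE
  isMax[, c(1:(m + 1), (W - m):W)] <- FALSE
  kp <- which(isMax, arr.ind = TRUE)
  if (!nrow(kp)) return(empty)
  ord <- order(R[kp], decreasing = TRUE)
  kp <- kp[ord[seq_len(min(nrow(kp), maxKeypoints))], , drop = FALSE]
  desc <- t(apply(kp, 1, function(p) .describePatch(gx, gy, p[1], p[2])))
  if (nrow(kp) == 1) desc <- matrix(desc, nrow = 1)
  attr(desc, "coords") <- cbind(x = kp[, 2], y = kp[, 1])
  desc
}

## Orientation-normalised 4x4x8 gradient histogram around (y, x).
.describePatch <- function(gx, gy, y, x) {
  m <- .PATCH_HALF
  px <- gx[(y - m):(y + m - 1), (x - m):(x + m - 1)]
  py <- gy[(y - m):(y + m - 1), (x - m):(x + m - 1)]
  mag <- sqrt(px^2 + py^2)
  ang <- atan2(py, px)
  ## dominant orientation from a 36-bin weighted histogram
  ob <- floor((ang + pi) / (2 * pi) * 36) %% 36
  w <- vapply(0:35, function(b) sum(mag[ob == b]), numeric(1))
  theta <- (which.max(w) - 0.5) / 36 * 2 * pi - pi
  rel <- (ang - theta) %% (2 * pi)
  bins <- floor(rel / (2 * pi) * 8) %% 8
  ## rotate cell coordinates by -theta so the grid follows the orientation
  yy <- matrix(rep(-m:(m - 1), 2 * m), 2 * m, 2 * m) + 0.5
  xx <- t(yy)
  xr <- cos(-theta) * xx - sin(-theta) * yy
  yr <- sin(-theta) * xx + cos(-theta) * yy
  cx <- pmin(pmax(floor((xr + m) / (2 * m / 4)), 0), 3)
  cy <- pmin(pmax(floor((yr + m) / (2 * m / 4)), 0), 3)
  cell <- cy * 4 + cx
  d <- numeric(.DESCRIPTOR_DIM)
  idx <- cell * 8 + bins + 1
  for (i in seq_along(idx)) d[idx[i]] <- d[idx[i]] + mag[i]
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d <- pmin(d, 0.2)
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d
}

#' Learn a visual-word codebook
#'
#' k-means over a descriptor sample (default dictionary size 4000 codewords).
#' Deterministic under a fixed seed; a sample smaller than \code{k} is
#' rejected with guidance to lower \code{k}.
#'
#' @param descriptors matrix (n x d) of descriptors, n >= k.
#' @param k dictionary size.
#' @param seed integer seed.
#' @param iterMax Lloyd iterations.
#' @return a [Codebook-class].
#' @export
buildCodebook <- function(descriptors, k = 4000L, seed = 0L, iterMax = 25L) {
  if (nrow(descriptors) < k)
    stop("descriptor sample (", nrow(descriptors), ") is smaller than k = ",
         k, "; lower k or supply more images")
  km <- NULL
  for (attempt in 0:2) {
    km <- withSeed(recordSeed(seed, attempt), tryCatch(
      suppressWarnings(stats::kmeans(descriptors, centers = k,
                                     iter.max = iterMax,
                                     algorithm = "Lloyd", nstart = 1)),
      error = function(e) NULL))
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " centres")
  new("Codebook", centers = unname(km$centers), seed = as.integer(seed))
}

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d codewords, descriptor dim %d (seed %d)\n",
              nrow(object@centers), ncol(object@centers), object@seed))
})

#' Encode an image as a bag-of-features histogram
#'
#' Assigns each descriptor to its nearest codeword (ties to the lower index)
#' and returns the L1-normalised count histogram; an image with no keypoints
#' yields an all-zero histogram with a warning.
#'
#' @param image H x W x 3 array, or a precomputed descriptor matrix.
#' @param codebook a [Codebook-class].
#' @return numeric vector of length k, summing to 1 (or all zero).
#' @export
encodeBoF <- function(image, codebook) {
  desc <- if (is.matrix(image) && length(dim(image)) == 2) image
          else extractDescriptors(image)
  k <- nrow(codebook@centers)
  if (ncol(desc) != ncol(codebook@centers) && nrow(desc))
    stop("descriptor dimension does not match the codebook")
  if (!nrow(desc)) {
    warning("no keypoints found; returning an all-zero histogram")
    return(numeric(k))
  }
  ## squared distances via the expansion |d - c|^2 = |d|^2 - 2 d.c + |c|^2
  cross <- desc %*% t(codebook@centers)
  d2 <- outer(rowSums(desc^2), rep(1, k)) - 2 * cross +
        outer(rep(1, nrow(desc)), rowSums(codebook@centers^2))
  nearest <- max.col(-d2, ties.method = "first")
  h <- tabulate(nearest, nbins = k)
  h / sum(h)
}

#' Fit a one-vs-rest polynomial-kernel SVM
#'
#' One binary SVM per class (polynomial kernel, default degree 3, cost 1);
#' prediction takes the class with the largest decision value.
#'
#' @param histograms matrix (n x k) of BoF histograms.
#' @param labels class labels (>= 2 classes).
#' @param degree polynomial degree.
#' @param cost regularisation parameter C.
#' @return list with per-class models and class names (used by
#'   [predictSvm()]).
#' @export
fitSvm <- function(histograms, labels, degree = 3, cost = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("SVM training requires at least 2 classes")
  models <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(histograms, y, kernel = "polynomial", degree = degree,
               coef0 = 1, cost = cost, scale = FALSE)
  })
  names(models) <- classes
  list(models = models, classes = classes, degree = degree, cost = cost)
}

#' @rdname fitSvm
#' @param fit a fitted one-vs-rest SVM (from \code{fitSvm}).
#' @param newHistograms matrix of histograms to score.
#' @return \code{predictSvm}: list with \code{class} (character vector) and
#'   \code{scores} (decision-value matrix, one column per class).
#' @export
predictSvm <- function(fit, newHistograms) {
  if (is.null(dim(newHistograms)))
    newHistograms <- matrix(newHistograms, nrow = 1)
  scores <- vapply(fit$classes, function(cl) {
    p <- stats::predict(fit$models[[cl]], newHistograms,
                        decision.values = TRUE)
    dv <- attr(p, "decision.values")
    ## e1071 labels the binary decision by level order; flip if needed
    if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
  }, numeric(nrow(newHistograms)))
  if (nrow(newHistograms) == 1) scores <- matrix(scores, nrow = 1,
                                                 dimnames = list(NULL, fit$classes))
  idx <- max.col(scores, ties.method = "first")
  list(class = fit$classes[idx], scores = scores)
}

#' Train a bag-of-features wing classifier
#'
#' The full classical pipeline: descriptors from every training image, a
#' codebook (k-means), histogram encoding and a one-vs-rest polynomial SVM,
#' wrapped in the common [WingClassifier-class] interface.
#'
#' @param images list of H x W x 3 arrays.
#' @param labels class labels.
#' @param k dictionary size (the default honours the 4000-codeword
#'   dictionary; tests use smaller values via this argument).
#' @param degree,cost SVM hyper-parameters.
#' @param seed integer seed.
#' @param level taxonomic level tag.
#' @return a [WingClassifier-class] with backend "bof".
#' @export
trainBofClassifier <- function(images, labels, k = 4000L, degree = 3,
                               cost = 1, seed = 0L, level = "subspecies") {
  descs <- lapply(images, extractDescriptors)
  all <- do.call(rbind, descs)
  cb <- buildCodebook(all, k = k, seed = seed)
  hist <- t(vapply(descs, function(d) {
    if (!nrow(d)) numeric(k) else suppressWarnings(encodeBoF(d, cb))
  }, numeric(k)))
  fit <- fitSvm(hist, labels, degree = degree, cost = cost)
  new("WingClassifier", backend = "bof",
      model = list(codebook = cb, svm = fit, k = k),
      classes = fit$classes, level = level)
}

.bofForwardProbs <- function(classifier, images) {
  cb <- classifier@model$codebook
  k <- nrow(cb@centers)
  hist <- t(vapply(images, function(im) {
    d <- extractDescriptors(im)
    if (!nrow(d)) numeric(k) else suppressWarnings(encodeBoF(d, cb))
  }, numeric(k)))
  pr <- predictSvm(classifier@model$svm, hist)
  ## softmax over decision values as pseudo-probabilities
  s <- exp(pr$scores - apply(pr$scores, 1, max))
  p <- s / rowSums(s)
  colnames(p) <- classifier@classes
  p
}

#' Persist / load a codebook
#'
#' Flat binary matrix with a one-line text header (k, d, seed).
#'
#' @param codebook a [Codebook-class].
#' @param file path.
#' @export
writeCodebook <- function(codebook, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- sprintf("codebook %d %d %d\n", nrow(codebook@centers),
                 ncol(codebook@centers), codebook@seed)
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(codebook@centers), con, size = 8)
  invisible(file)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- ""
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch) || ch == "\n") break
    hdr <- paste0(hdr, ch)
  }
  p <- as.integer(strsplit(hdr, " ")[[1]][-1])
  vals <- readBin(con, numeric(), n = p[1] * p[2], size = 8)
  new("Codebook", centers = matrix(vals, p[1], p[2]), seed = p[3])
}
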
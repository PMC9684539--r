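## Internal image and RNG utilities shared across modules.

.clip01 <- function(x) pmin(pmax(x, 0), 1)

## Evaluate expr under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Counter-based per-record seed derivation: records are independent of
## generation order and reproducible from (master seed, counter) alone.
recordSeed <- function(master, counter) {
  as.integer((as.numeric(master) + 131071 * as.numeric(counter)) %%
             .Machine$integer.max)
}

## 1-D Gaussian kernel, trimmed at 3 sigma, normalised to sum 1.
.gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-m:m) / sigma)^2)
  k / sum(k)
}

## Separable Gaussian blur of a matrix with reflective boundary handling
## (the kernel is normalised, so the image mean is preserved).
.blurMatrix <- function(X, sigma) {
  k <- .gaussKernel1d(sigma)
  m <- (length(k) - 1L) / 2L
  if (m == 0) return(X)
  conv1 <- function(M, k, m) {           # along rows (first dim)
    H <- nrow(M)
    top <- M[m:1, , drop = FALSE]
    bot <- M[H:(H - m + 1), , drop = FALSE]
    P <- rbind(top, M, bot)
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * P[j:(j + H - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(X, k, m)), k, m))
}

.blurImage <- function(img, sigma) {
  for (c in 1:3) img[, , c] <- .blurMatrix(img[, , c], sigma)
  img
}

## 2-D convolution of each channel with an arbitrary kernel (reflect padding).
.conv2dImage <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  mh <- (kh - 1L) %/% 2L; mw <- (kw - 1L) %/% 2L
  H <- dim(img)[1]; W <- dim(img)[2]
  for (c in 1:3) {
    X <- img[, , c]
    P <- rbind(X[(mh:1), , drop = FALSE], X,
               X[H:(H - mh + 1), , drop = FALSE])
    P <- cbind(P[, (mw:1), drop = FALSE], P,
               P[, W:(W - mw + 1), drop = FALSE])
    out <- matrix(0, H, W)
    for (i in seq_len(kh)) for (j in seq_len(kw))
      if (kern[i, j] != 0)
        out <- out + kern[i, j] * P[i:(i + H - 1), j:(j + W - 1)]
    img[, , c] <- out
  }
  img
}

## Bilinear sampling of img (H x W x 3) at source coordinates (sy, sx);
## out-of-range samples take `fill`.
.sampleBilinear <- function(img, sy, sx, fill = 0) {
  H <- dim(img)[1]; W <- dim(img)[2]
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  inside <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  y0c <- cl(y0, 1, H); y1c <- cl(y0 + 1, 1, H)
  x0c <- cl(x0, 1, W); x1c <- cl(x0 + 1, 1, W)
  n <- length(sy)
  out <- array(fill, c(n, 3))
  for (c in 1:3) {
    ch <- img[, , c]
    v <- (1 - fy) * (1 - fx) * ch[cbind(y0c, x0c)] +
         (1 - fy) * fx       * ch[cbind(y0c, x1c)] +
         fy * (1 - fx)       * ch[cbind(y1c, x0c)] +
         fy * fx             * ch[cbind(y1c, x1c)]
    out[, c] <- ifelse(inside, v, fill)
  }
  out
}

## Bilinear resize to (h, w); identity when the size already matches.
.resizeBilinear <- function(img, h, w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H == h && W == w) return(img)
  yo <- ((seq_len(h) - 0.5) * H / h) + 0.5 - 0.5  # centre-aligned
  xo <- ((seq_len(w) - 0.5) * W / w) + 0.5 - 0.5
  grid <- expand.grid(y = yo, x = xo)
  smp <- .sampleBilinear(img, pmin(pmax(grid$y, 1), H),
                         pmin(pmax(grid$x, 1), W))
  array(smp, c(h, w, 3))
}

## Inverse-mapped affine warp about the image centre: rotation (degrees,
## counter-clockwise) and isotropic zoom, same output size, `fill` outside.
.warpRotateZoom <- function(img, angle, zoom, fill = 0) {
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  dy <- grid$y - cy; dx <- grid$x - cx
  ## inverse map: un-zoom then un-rotate
  sy <- cy + ( cos(th) * dy - sin(th) * dx) / zoom
  sx <- cx + ( sin(th) * dy + cos(th) * dx) / zoom
  smp <- .sampleBilinear(img, sy, sx, fill = fill)
  array(smp, c(H, W, 3))
}

.flipH <- function(img) img[, dim(img)[2]:1, , drop = FALSE]
.flipV <- function(img) img[dim(img)[1]:1, , , drop = FALSE]

.rgb2gray <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}
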
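## Colorimetric integration: reflectance spectra -> sRGB.
##
## The CIE 1931 2-degree colour-matching functions are evaluated with the
## multi-lobe Gaussian analytic fits of Wyman, Sloan & Shirley (2013), which
## reproduce the tabulated observer to within ~1% and keep the package free of
## large data tables.  The D65 illuminant is the standard 10 nm table.

.cieGaussLobe <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 colour-matching functions
#'
#' Evaluate the CIE 1931 2-degree standard observer at arbitrary wavelengths
#' using compact analytic fits.
#'
#' @param wavelength numeric vector of wavelengths in nm.
#' @return a matrix with columns \code{x}, \code{y}, \code{z}.
#' @export
cieXYZBar <- function(wavelength) {
  w <- as.numeric(wavelength)
  xb <- 1.056 * .cieGaussLobe(w, 599.8, 37.9, 31.0) +
        0.362 * .cieGaussLobe(w, 442.0, 16.0, 26.7) -
        0.065 * .cieGaussLobe(w, 501.1, 20.4, 26.2)
  yb <- 0.821 * .cieGaussLobe(w, 568.8, 46.9, 40.5) +
        0.286 * .cieGaussLobe(w, 530.9, 16.3, 31.1)
  zb <- 1.217 * .cieGaussLobe(w, 437.0, 11.8, 36.0) +
        0.681 * .cieGaussLobe(w, 459.0, 26.0, 13.8)
  cbind(x = pmax(xb, 0), y = pmax(yb, 0), z = pmax(zb, 0))
}

## CIE standard illuminant D65, relative spectral power, 380..780 nm step 10.
.d65Table <- cbind(
  wl = seq(380, 780, by = 10),
  S = c(49.98, 54.65, 82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81,
        114.86, 115.92, 108.81, 109.35, 107.80, 104.79, 107.69, 104.41,
        104.05, 100.00, 96.33, 95.79, 88.69, 90.01, 89.60, 87.70, 83.29,
        83.70, 80.03, 80.21, 82.28, 78.28, 69.72, 71.61, 74.35, 61.60,
        69.89, 75.09, 63.59, 46.42, 66.81, 63.38)
)

#' D65 illuminant spectral power
#'
#' Relative spectral power of CIE illuminant D65, linearly interpolated from
#' the standard 10 nm table (normalised to 100 at 560 nm).
#'
#' @param wavelength numeric vector of wavelengths in nm (380--780).
#' @return numeric vector of relative power.
#' @export
illuminantD65 <- function(wavelength) {
  stats::approx(.d65Table[, "wl"], .d65Table[, "S"], xout = wavelength,
                rule = 2)$y
}

## sRGB <-> XYZ (D65 white), IEC 61966-2-1
.M_XYZ2RGB <- matrix(c( 3.2406, -1.5372, -0.4986,
                       -0.9689,  1.8758,  0.0415,
                        0.0557, -0.2040,  1.0570), 3, 3, byrow = TRUE)
.M_RGB2XYZ <- matrix(c(0.4124, 0.3576, 0.1805,
                       0.2126, 0.7152, 0.0722,
                       0.0193, 0.1192, 0.9505), 3, 3, byrow = TRUE)
.XYZ_WHITE_SRGB <- c(0.95047, 1.00000, 1.08883)

.srgbEncode <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.srgbDecode <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Convert reflectance spectra to sRGB
#'
#' Integrates reflectance spectra against the configured illuminant and the
#' CIE 1931 observer, applies von Kries white-point normalisation (so a
#' unit-reflectance spectrum maps exactly to neutral white) and encodes to
#' gamma-corrected sRGB.
#'
#' @param reflectance numeric vector (one spectrum) or matrix with one row per
#'   spectrum and one column per wavelength-grid point.
#' @param optics an [OpticalConfig-class] supplying the wavelength grid and
#'   illuminant.
#' @return a matrix with columns \code{r}, \code{g}, \code{b} in \[0, 1\]
#'   (one row per input spectrum).
#' @examples
#' oc <- opticalConfig()
#' spectrumToRGB(rep(1, length(wavelengthGrid(oc))), oc)  # neutral white
#' @export
spectrumToRGB <- function(reflectance, optics) {
  stopifnot(is(optics, "OpticalConfig"))
  wl <- optics@wavelength_grid
  if (is.null(dim(reflectance))) reflectance <- matrix(reflectance, nrow = 1)
  if (ncol(reflectance) != length(wl))
    stop("spectrum length (", ncol(reflectance),
         ") does not match the wavelength grid (", length(wl), ")")
  if (any(reflectance < -1e-12) || any(reflectance > 1 + 1e-12))
    stop("reflectance values must lie in [0, 1]")
  cmf <- cieXYZBar(wl)
  S <- optics@illuminant
  ## trapezoidal quadrature weights on a possibly non-uniform grid
  qw <- .trapWeights(wl)
  W <- cmf * (S * qw)               # per-wavelength XYZ weights
  xyz_n <- colSums(W)               # illuminant white point
  xyz <- reflectance %*% W          # n x 3
  ## von Kries: express relative to the illuminant white, then re-apply the
  ## sRGB D65 white so that flat-1 reflectance is exactly (1,1,1)
  xyz <- sweep(xyz, 2, xyz_n, "/")
  xyz <- sweep(xyz, 2, .XYZ_WHITE_SRGB, "*")
  lin <- xyz %*% t(.M_XYZ2RGB)
  out <- .srgbEncode(lin)
  colnames(out) <- c("r", "g", "b")
  out
}

.trapWeights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  d <- diff(x)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

## sRGB (gamma) -> CIE LCh(ab), D65 white; used by the CIE-noise perturbation
.srgb2lch <- function(rgb) {
  lin <- .srgbDecode(rgb)
  xyz <- lin %*% t(.M_RGB2XYZ)
  xyz <- sweep(xyz, 2, .XYZ_WHITE_SRGB, "/")
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1]); fy <- f(xyz[, 2]); fz <- f(xyz[, 3])
  L <- 116 * fy - 16
  a <- 500 * (fx - fy)
  b <- 200 * (fy - fz)
  cbind(L = L, C = sqrt(a^2 + b^2), h = atan2(b, a))
}

.lch2srgb <- function(lch) {
  a <- lch[, 2] * cos(lch[, 3])
  b <- lch[, 2] * sin(lch[, 3])
  fy <- (lch[, 1] + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .XYZ_WHITE_SRGB, "*")
  lin <- xyz %*% t(.M_XYZ2RGB)
  .srgbEncode(pmin(pmax(lin, 0), 1))
}
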
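## Thin-film interference model.
##
## A wing membrane in air is a single dielectric film with two interfaces.
## Light reflected at the top interface interferes with light transmitted,
## reflected at the bottom interface and transmitted back out.  The package
## models the two leading beams: amplitude r at the first interface and
## -(1 - r^2) r e^{i delta} for the second (Fresnel amplitude coefficients,
## one internal round trip, with the phase delta = 4 pi n d cos(theta_t) /
## lambda and the half-wave shift of the external reflection).  Higher-order
## internal bounces carry amplitude r^3 and below and are neglected; the test
## suite bounds the error against the exact multi-beam (Airy) solution.

#' Construct an optical configuration
#'
#' Defaults model the acquisition geometry used for tsetse wings: a
#' chitin-like membrane index of 1.5 in air, 10 degree illumination
#' incidence, D65 illumination sampled every 10 nm across the visible range.
#'
#' @param filmIndex refractive index of the membrane.
#' @param ambientIndex refractive index of the surrounding medium.
#' @param incidenceAngle illumination incidence in degrees from the normal.
#' @param wavelengthGrid increasing wavelengths in nm within \[380, 780\].
#' @param illuminant relative spectral power per grid point; defaults to D65.
#' @return an [OpticalConfig-class] object.
#' @examples
#' oc <- opticalConfig()
#' filmIndex(oc)
#' @export
opticalConfig <- function(filmIndex = 1.5, ambientIndex = 1.0,
                          incidenceAngle = 10,
                          wavelengthGrid = seq(380, 780, by = 10),
                          illuminant = illuminantD65(wavelengthGrid)) {
  new("OpticalConfig",
      film_refractive_index = filmIndex,
      ambient_refractive_index = ambientIndex,
      incidence_angle = incidenceAngle,
      wavelength_grid = as.numeric(wavelengthGrid),
      illuminant = as.numeric(illuminant))
}

#' @describeIn opticalConfig membrane refractive index accessor.
#' @param object an \code{OpticalConfig}.
#' @export
filmIndex <- function(object) object@film_refractive_index

#' @describeIn opticalConfig wavelength grid accessor (nm).
#' @export
wavelengthGrid <- function(object) object@wavelength_grid

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig: n_film =", object@film_refractive_index,
      "| n_ambient =", object@ambient_refractive_index,
      "| incidence =", object@incidence_angle, "deg\n",
      " wavelengths:", length(object@wavelength_grid), "points in [",
      min(object@wavelength_grid), ",", max(object@wavelength_grid), "] nm\n")
})

#' Thin-film reflectance
#'
#' Unpolarised reflectance of a free-standing dielectric film (the wing
#' membrane in air) for given thickness and wavelength, from the two-beam
#' interference model with Fresnel amplitude coefficients.  At normal
#' incidence the reflectance is periodic in thickness with period
#' \eqn{\lambda / (2 n_{film})}; a quarter-wave film
#' (\eqn{d = \lambda / (4 n_{film})}) reflects maximally.
#'
#' Arguments are vectorised and recycled against each other.
#'
#' @param thickness film thickness in nm (>= 0).
#' @param wavelength vacuum wavelength in nm.
#' @param optics an [OpticalConfig-class].
#' @return reflectance fraction(s) in \[0, 1\].
#' @examples
#' oc <- opticalConfig()
#' thinFilmReflectance(550 / (4 * 1.5), 550, oc)  # quarter-wave maximum
#' @export
thinFilmReflectance <- function(thickness, wavelength, optics = opticalConfig()) {
  stopifnot(is(optics, "OpticalConfig"))
  if (any(thickness < 0)) stop("thickness must be >= 0")
  n1 <- optics@ambient_refractive_index
  n2 <- optics@film_refractive_index
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1 (non-physical index)")
  wl <- optics@wavelength_grid
  if (any(wavelength < min(wl) - 1e-9) || any(wavelength > max(wl) + 1e-9))
    stop("wavelength outside the configured grid range")
  th_i <- optics@incidence_angle * pi / 180
  sin_t <- n1 * sin(th_i) / n2           # Snell refraction into the film
  cos_t <- sqrt(1 - sin_t^2)
  cos_i <- cos(th_i)
  ## Fresnel amplitude reflection, ambient -> film
  rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
  rp <- (n2 * cos_i - n1 * cos_t) / (n2 * cos_i + n1 * cos_t)
  delta <- 4 * pi * n2 * thickness * cos_t / wavelength
  beam2 <- function(r) {
    ## |r - (1 - r^2) r e^{i delta}|^2 ; the film->ambient reflection is -r
    r^2 * (1 + (1 - r^2)^2 - 2 * (1 - r^2) * cos(delta))
  }
  R <- (beam2(rs) + beam2(rp)) / 2
  pmin(pmax(R, 0), 1)
}
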
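## Parametric wing geometry and membrane-thickness fields.
##
## The wing outline is a half-ellipse: a straight leading edge at the top and
## an elliptical trailing margin below.  Two chordwise veins ("V" and "VI")
## at fixed relative span positions and the trailing-edge arc are carried as
## named polylines so the occlusion perturbations can crop at named
## anatomical boundaries.  Real Glossina venation is deliberately not
## reproduced; the geometry only has to provide stable, nameable landmarks.

.WING_LEAD_Y <- 0.18    # leading edge, fraction of image height
.WING_SEMI_B <- 0.72    # chordwise semi-axis, fraction of image height
.WING_SEMI_A <- 0.46    # spanwise semi-axis, fraction of image width
.WING_VEIN_V_U <- 0.70  # vein V, relative span position
.WING_VEIN_VI_U <- 0.35 # vein VI, relative span position
.WING_TRAIL_RHO <- 0.82 # trailing-edge band: elliptical radius ratio beyond this
.WIP_BACKGROUND <- 0.02 # dark, light-absorbing background level

## Geometry scaffold for an H x W image: mask, relative coordinates and the
## elliptical radius ratio of every pixel, plus the three named polylines.
wingGeometry <- function(imageSize) {
  H <- imageSize[1]; W <- imageSize[2]
  y0 <- .WING_LEAD_Y * H
  b <- .WING_SEMI_B * H
  cx <- 0.5 * W
  a <- .WING_SEMI_A * W
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  rho <- sqrt(((xs - cx) / a)^2 + ((ys - y0) / b)^2)
  mask <- (ys >= y0) & (rho <= 1)
  u <- (xs - (cx - a)) / (2 * a)     # 0..1 across the span
  v <- (ys - y0) / b                 # 0..1 leading edge -> trailing tip
  ## polylines in pixel coordinates (x, y)
  vline <- function(urel) {
    x <- cx - a + urel * 2 * a
    ymax <- y0 + b * sqrt(max(0, 1 - ((x - cx) / a)^2))
    yy <- seq(y0, ymax, length.out = 25)
    cbind(x = rep(x, 25), y = yy)
  }
  th <- seq(0, pi, length.out = 60)
  trail <- cbind(x = cx + a * cos(th), y = y0 + b * sin(th))
  list(H = H, W = W, mask = mask, u = u, v = v, rho = rho,
       aspect = b / (2 * a),
       veins = list(V = vline(.WING_VEIN_V_U),
                    VI = vline(.WING_VEIN_VI_U),
                    trailing_edge = trail))
}

#' Generate a membrane-thickness map from a species template
#'
#' Builds the per-pixel thickness field for one specimen: the template's base
#' thickness, Gaussian-profile thickness patches (the species-specific
#' coloured regions), a constant sex offset for males (faint sexual
#' dimorphism), narrow vein ridges along veins V and VI, and a smooth
#' per-specimen Gaussian random field (low-pass filtered white noise) of
#' amplitude \code{noise_scale}.  Deterministic for fixed
#' (template, sex, imageSize, seed).
#'
#' @param template a [SpeciesTemplate-class].
#' @param sex "male" or "female".
#' @param imageSize integer (H, W); default c(116, 256).
#' @param seed integer seed for the specimen noise field.
#' @return a [ThicknessMap-class].
#' @examples
#' tpl <- wellSeparatedTemplates(2)[[1]]
#' tm <- generateThicknessMap(tpl, "female", c(58, 128), seed = 1)
#' @export
generateThicknessMap <- function(template, sex = c("female", "male"),
                                 imageSize = c(116L, 256L), seed = 0L) {
  stopifnot(is(template, "SpeciesTemplate"))
  validObject(template)
  sex <- match.arg(sex)
  if (any(imageSize <= 0)) stop("imageSize must be positive")
  g <- wingGeometry(imageSize)
  th <- matrix(template@base_thickness, g$H, g$W)
  p <- template@patches
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      du <- g$u - p$u[i]
      dv <- (g$v - p$v[i]) * g$aspect      # pixel-isotropic distance
      d2 <- du^2 + dv^2
      sig <- p$radius[i] / 2
      th <- th + p$delta[i] * exp(-0.5 * d2 / sig^2)
    }
  }
  if (sex == "male") th <- th + template@sex_offset
  if (template@noise_scale > 0) {
    field <- withSeed(seed, matrix(stats::rnorm(g$H * g$W), g$H, g$W))
    field <- .blurMatrix(field, sigma = 0.05 * g$W)
    s <- stats::sd(field)
    if (s > 0) field <- field / s
    field <- pmin(pmax(field, -3), 3)
    th <- th + template@noise_scale * field
  }
  ## vein ridges: slightly thicker sclerotised lines, visible as colour lines
  for (uu in c(.WING_VEIN_V_U, .WING_VEIN_VI_U)) {
    near <- abs(g$u - uu) < 0.008
    th[near] <- th[near] + 120
  }
  th <- pmax(th, 0)
  th[!g$mask] <- 0
  new("ThicknessMap", grid = th, mask = g$mask, veins = g$veins)
}

setMethod("show", "ThicknessMap", function(object) {
  d <- dim(object@grid)
  rng <- range(object@grid[object@mask])
  cat(sprintf("ThicknessMap %d x %d px | wing area %d px | thickness %.0f-%.0f nm | veins: %s\n",
              d[1], d[2], sum(object@mask), rng[1], rng[2],
              paste(names(object@veins), collapse = ", ")))
})
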
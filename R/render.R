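## Rendering: thickness field -> interference colours -> sRGB image.

#' Render a wing image from a thickness map
#'
#' Every in-mask pixel gets the colour of its thin-film reflectance spectrum
#' (colorimetrically integrated to sRGB); pixels outside the mask are the
#' dark, light-absorbing background the patterns are photographed against.
#'
#' @param tmap a [ThicknessMap-class].
#' @param optics an [OpticalConfig-class].
#' @param genus,complex,species,subspecies taxonomic label carried on the
#'   output.
#' @param sex "male" or "female".
#' @param seed integer seed recorded on the output (provenance only; the
#'   render itself is deterministic).
#' @param templateId id of the generating template.
#' @return a [RenderedWing-class].
#' @export
renderWing <- function(tmap, optics = opticalConfig(), genus = "Glossina",
                       complex = NA_character_, species = "sp",
                       subspecies = NA_character_,
                       sex = c("female", "male"), seed = 0L,
                       templateId = "template") {
  stopifnot(is(tmap, "ThicknessMap"))
  validObject(tmap)
  sex <- match.arg(sex)
  H <- nrow(tmap@grid); W <- ncol(tmap@grid)
  img <- array(.WIP_BACKGROUND, c(H, W, 3))
  idx <- which(tmap@mask)
  if (length(idx)) {
    d <- tmap@grid[idx]
    wl <- optics@wavelength_grid
    ## unique thickness values cut the spectral work dramatically on maps
    ## with repeated values (flat regions, quantised fields)
    ud <- unique(d)
    R <- vapply(wl, function(l) thinFilmReflectance(ud, l, optics),
                numeric(length(ud)))
    if (length(ud) == 1) R <- matrix(R, nrow = 1)
    rgb <- spectrumToRGB(R, optics)
    rows <- match(d, ud)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[idx] <- pmax(rgb[rows, c], .WIP_BACKGROUND)
      img[, , c] <- ch
    }
  }
  new("RenderedWing", image = .clip01(img), genus = genus,
      complex = as.character(complex), species = species,
      subspecies = as.character(subspecies), sex = sex,
      seed = as.integer(seed), template_id = templateId)
}

#' Acquisition-style post-processing
#'
#' Mimics the contrast and saturation adjustments applied when photographs
#' are prepared for the database (the synthetic analogue of the microscope
#' post-processing stage).  The robustness conditions "raw picture" and
#' "resized raw picture" bypass this step.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param contrast,saturation gain factors (> 1 boosts).
#' @return adjusted image, clipped to \[0, 1\].
#' @export
acquisitionAdjust <- function(img, contrast = 1.15, saturation = 1.2) {
  m <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  for (c in 1:3) img[, , c] <- m + (img[, , c] - m) * saturation
  img <- 0.5 + (img - 0.5) * contrast
  .clip01(img)
}

setMethod("show", "RenderedWing", function(object) {
  d <- dim(object@image)
  lab <- paste(stats::na.omit(c(object@genus, object@species,
                                object@subspecies)), collapse = " ")
  cat(sprintf("RenderedWing %d x %d | %s (%s) | template %s, seed %d\n",
              d[1], d[2], lab, object@sex, object@template_id, object@seed))
})
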
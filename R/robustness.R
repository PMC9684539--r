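## Image-perturbation robustness: the 15-condition grid with traffic-light
## scoring of identification stability.
##
## Condition vocabulary: the descriptive names (spread, hurl, rgb_noise,
## cie_noise) and the alternative legend vocabulary (scatter, throws,
## scrambling_rvb, scrambling_cie) name the same operations; both are
## accepted when building a TransformSpec.

.TRANSFORM_ALIASES <- c(scatter = "spread", throws = "hurl",
                        scrambling_rvb = "rgb_noise",
                        scrambling_cie = "cie_noise")

.TRANSFORM_DEFAULTS <- list(
  gaussian_blur = list(sigma = 2),
  lens_blur = list(radius = 4, offset = c(1, 1)),
  video_distortion = list(period = 3, amplitude = 0.5),
  spread = list(radius = 3, seed = 0L),
  hurl = list(probability = 0.1, seed = 0L),
  rgb_noise = list(sd = 0.08, seed = 0L),
  cie_noise = list(sdL = 6, sdC = 6, sdH = 0.15, seed = 0L)
)

#' Construct a transform specification
#'
#' @param kind one of the 15 condition kinds (legend aliases such as
#'   "scatter" or "throws" are accepted).
#' @param ... kind-specific parameters overriding the pinned defaults
#'   (\code{sigma}, \code{radius}, \code{offset}, \code{period},
#'   \code{amplitude}, \code{probability}, \code{sd}, \code{sdL},
#'   \code{sdC}, \code{sdH}, \code{seed}).
#' @return a [TransformSpec-class].
#' @export
transformSpec <- function(kind, ...) {
  if (kind %in% names(.TRANSFORM_ALIASES)) kind <- .TRANSFORM_ALIASES[[kind]]
  params <- utils::modifyList(
    if (kind %in% names(.TRANSFORM_DEFAULTS)) .TRANSFORM_DEFAULTS[[kind]]
    else list(),
    list(...))
  new("TransformSpec", kind = kind, params = params)
}

#' The 15-condition robustness grid
#'
#' Conditions in legend order: no transformation, gaussian blur, lens blur,
#' video distortion, spread (scatter), hurl (throws), RGB noise, CIE noise,
#' the three partial-wing occlusions (trailing edge, outer part at vein V,
#' inner part at vein VI), the raw unprocessed picture, horizontal and
#' vertical flips, and the resized raw picture.
#'
#' @param ... per-kind parameter overrides, named by kind
#'   (e.g. \code{gaussian_blur = list(sigma = 3)}).
#' @return list of 15 [TransformSpec-class] objects, named by kind.
#' @export
robustnessGrid <- function(...) {
  over <- list(...)
  specs <- lapply(.TRANSFORM_KINDS, function(k)
    do.call(transformSpec, c(list(kind = k),
                             if (k %in% names(over)) over[[k]] else list())))
  names(specs) <- .TRANSFORM_KINDS
  specs
}

#' Apply a perturbation to an image
#'
#' All perturbations keep the image shape, clip values to \[0, 1\] and are
#' pure functions of (image, params, seed).  The occlusion kinds fill the
#' removed wing region with the dark background; the raw-picture kinds are
#' identities at this level (the bypass of acquisition post-processing is
#' applied upstream by [evaluateRobustness()], which re-renders from the
#' generating template).
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param spec a [TransformSpec-class].
#' @return transformed image, same shape.
#' @export
applyTransform <- function(image, spec) {
  stopifnot(is(spec, "TransformSpec"))
  validObject(spec)
  p <- spec@params
  out <- switch(spec@kind,
    none = , raw_unprocessed = , raw_resized = image,
    gaussian_blur = .blurImage(image, p$sigma),
    lens_blur = .lensBlur(image, p$radius, p$offset),
    video_distortion = {
      rows <- which(seq_len(dim(image)[1]) %% p$period == 0)
      image[rows, , ] <- image[rows, , ] * (1 - p$amplitude)
      image
    },
    spread = .spreadPixels(image, p$radius, p$seed),
    hurl = .hurlPixels(image, p$probability, p$seed),
    rgb_noise = withSeed(p$seed, image + array(stats::rnorm(length(image),
                                                            sd = p$sd),
                                               dim(image))),
    cie_noise = .cieNoise(image, p$sdL, p$sdC, p$sdH, p$seed),
    occlude_trailing_edge = occludeWing(image, "trailing_edge"),
    occlude_outer_vein_V = occludeWing(image, "outer_at_vein_V"),
    occlude_inner_vein_VI = occludeWing(image, "inner_at_vein_VI"),
    flip_h = .flipH(image),
    flip_v = .flipV(image),
    stop("unknown transform kind: ", spec@kind))
  .clip01(out)
}

## Off-centre disk ("bokeh") blur: the closest standard operation to a
## decentred lens.
.lensBlur <- function(image, radius, offset) {
  r <- ceiling(radius)
  size <- 2 * r + 1 + 2 * max(abs(offset))
  if (size %% 2 == 0) size <- size + 1
  c0 <- (size + 1) / 2
  yy <- matrix(seq_len(size), size, size) - c0 - offset[1]
  xx <- t(matrix(seq_len(size), size, size)) - c0 - offset[2]
  K <- (yy^2 + xx^2) <= radius^2
  K <- K / sum(K)
  .conv2dImage(image, K)
}

## Swap each pixel with a randomly chosen pixel in proximity: a permutation
## of pixel positions, so per-channel value multisets are preserved exactly.
.spreadPixels <- function(image, radius, seed) {
  H <- dim(image)[1]; W <- dim(image)[2]
  n <- H * W
  withSeed(seed, {
    dy <- sample(-radius:radius, n, replace = TRUE)
    dx <- sample(-radius:radius, n, replace = TRUE)
  })
  ys <- pmin(pmax(rep(seq_len(H), W) + dy, 1), H)
  xs <- pmin(pmax(rep(seq_len(W), each = H) + dx, 1), W)
  target <- (xs - 1L) * H + ys
  perm <- seq_len(n)
  for (i in seq_len(n)) {          # sequential swaps form a permutation
    j <- target[i]
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
  }
  out <- image
  for (c in 1:3) {
    ch <- image[, , c]
    out[, , c] <- matrix(ch[perm], H, W)
  }
  out
}

## Pixels have a chance to get replaced by random colour values.
.hurlPixels <- function(image, probability, seed) {
  if (probability == 0) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  withSeed(seed, {
    hit <- stats::runif(H * W) < probability
    vals <- matrix(stats::runif(sum(hit) * 3), ncol = 3)
  })
  for (c in 1:3) {
    ch <- image[, , c]
    ch[hit] <- vals[, c]
    image[, , c] <- ch
  }
  image
}

## Normally distributed noise in the Lightness / Chroma / Hue model,
## converted back with gamut clipping.
.cieNoise <- function(image, sdL, sdC, sdH, seed) {
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  lch <- .srgb2lch(px)
  withSeed(seed, {
    lch[, 1] <- lch[, 1] + stats::rnorm(nrow(lch), sd = sdL)
    lch[, 2] <- pmax(lch[, 2] + stats::rnorm(nrow(lch), sd = sdC), 0)
    lch[, 3] <- lch[, 3] + stats::rnorm(nrow(lch), sd = sdH)
  })
  lch[, 1] <- pmin(pmax(lch[, 1], 0), 100)
  out <- .lch2srgb(lch)
  array(out, c(H, W, 3))
}

#' Partial wing occlusion at named anatomical boundaries
#'
#' Crops the wing at one of the named boundaries -- deleting the trailing
#' edge, the outer part beyond vein V, or the inner part up to vein VI --
#' filling the removed region with the dark background.  Idempotent; the
#' wing-mask area strictly decreases.
#'
#' @param image H x W x 3 array.
#' @param mode "trailing_edge", "outer_at_vein_V" or "inner_at_vein_VI".
#' @param geometry a wing geometry (from the synthetic generator's layout);
#'   derived from the image size when NULL, since the synthetic wing layout
#'   is a fixed function of the frame.
#' @return occluded image.
#' @export
occludeWing <- function(image, mode = c("trailing_edge", "outer_at_vein_V",
                                        "inner_at_vein_VI"),
                        geometry = NULL) {
  mode <- match.arg(mode)
  if (is.null(geometry)) geometry <- wingGeometry(dim(image)[1:2])
  remove <- switch(mode,
    trailing_edge = geometry$mask & geometry$rho > .WING_TRAIL_RHO,
    outer_at_vein_V = geometry$mask & geometry$u > .WING_VEIN_V_U,
    inner_at_vein_VI = geometry$mask & geometry$u < .WING_VEIN_VI_U)
  for (c in 1:3) {
    ch <- image[, , c]
    ch[remove] <- .WIP_BACKGROUND
    image[, , c] <- ch
  }
  image
}

#' Evaluate identification robustness across the perturbation grid
#'
#' Scores a trained classifier on every record under every condition and
#' reports per-species accuracies with traffic-light codes: green for 100%
#' identification agreement, yellow below 100%, red for none, blank where a
#' species has no samples.  The "none" condition reproduces the model's
#' base per-species accuracy exactly.  When the generating templates are
#' supplied, the raw-picture conditions re-render each specimen without
#' acquisition post-processing (raw, and raw resized to the preprocessing
#' geometry); otherwise they fall back to the stored image.
#'
#' @param classifier a trained [WingClassifier-class].
#' @param manifest a [WingManifest-class] of records to score.
#' @param grid list of [TransformSpec-class] (default [robustnessGrid()]).
#' @param templates optional template list for the raw re-renders.
#' @param optics an [OpticalConfig-class] for re-rendering.
#' @param images optional pre-loaded images.
#' @return a [RobustnessReport-class].
#' @export
evaluateRobustness <- function(classifier, manifest, grid = robustnessGrid(),
                               templates = NULL, optics = opticalConfig(),
                               images = NULL) {
  stopifnot(is(classifier, "WingClassifier"))
  recs <- manifest@records
  if (!nrow(recs)) stop("no records to evaluate")
  if (is.null(images)) images <- loadImages(manifest)
  species <- coarsenLabel(recs, classifier@level)
  spNames <- sort(unique(species))
  rawImages <- NULL
  if (!is.null(templates) &&
      any(vapply(grid, function(s) s@kind %in% c("raw_unprocessed",
                                                 "raw_resized"), logical(1))))
    rawImages <- .rerenderRaw(recs, templates, optics,
                              dim(images[[1]])[1:2])
  acc <- matrix(NA_real_, length(spNames), length(grid),
                dimnames = list(spNames, names(grid)))
  for (j in seq_along(grid)) {
    spec <- grid[[j]]
    imgs <- if (spec@kind %in% c("raw_unprocessed", "raw_resized") &&
                !is.null(rawImages)) rawImages
            else lapply(images, applyTransform, spec = spec)
    if (spec@kind == "raw_resized")
      imgs <- lapply(imgs, .resizeBilinear, h = dim(images[[1]])[1],
                     w = dim(images[[1]])[2])
    pred <- predictWing(classifier, imgs)
    ok <- pred == species
    for (s in spNames) acc[s, j] <- mean(ok[species == s])
  }
  lights <- ifelse(is.na(acc), "blank",
            ifelse(acc == 1, "green", ifelse(acc == 0, "red", "yellow")))
  new("RobustnessReport", grid = acc, lights = lights)
}

.rerenderRaw <- function(recs, templates, optics, imageSize) {
  ids <- vapply(templates, function(t) t@template_id, character(1))
  lapply(seq_len(nrow(recs)), function(i) {
    tid <- sub("_[0-9]+$", "", recs$id[i])
    m <- match(tid, ids)
    if (is.na(m)) stop("no template for record ", recs$id[i])
    t <- templates[[m]]
    tm <- generateThicknessMap(t, recs$sex[i], imageSize, seed = recs$seed[i])
    renderWing(tm, optics, sex = recs$sex[i], seed = recs$seed[i],
               templateId = tid)@image
  })
}

setMethod("show", "RobustnessReport", function(object) {
  cat(sprintf("RobustnessReport: %d species x %d conditions\n",
              nrow(object@grid), ncol(object@grid)))
  tab <- table(factor(object@lights,
                      c("green", "yellow", "red", "blank")))
  cat("  lights:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Export a robustness report
#'
#' CSV of the accuracy grid plus a colour-coded HTML table of the lights.
#'
#' @param report a [RobustnessReport-class].
#' @param csvFile,htmlFile output paths (either may be NULL to skip).
#' @export
writeRobustnessReport <- function(report, csvFile = NULL, htmlFile = NULL) {
  if (!is.null(csvFile))
    utils::write.csv(report@grid, csvFile, quote = FALSE)
  if (!is.null(htmlFile)) {
    cols <- c(green = "#2ca02c", yellow = "#ffd92f", red = "#d62728",
              blank = "#ffffff")
    rows <- apply(cbind(rownames(report@lights), report@lights), 1,
      function(r) paste0("<tr><td>", r[1], "</td>",
        paste0("<td style='background:", cols[r[-1]], "'>",
               r[-1], "</td>", collapse = ""), "</tr>"))
    html <- c("<table border='1'>",
              paste0("<tr><th>species</th>",
                     paste0("<th>", colnames(report@lights), "</th>",
                            collapse = ""), "</tr>"),
              rows, "</table>")
    writeLines(html, htmlFile)
  }
  invisible(report)
}
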
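## Synthetic dataset generation: templates -> PNG images + CSV manifest.

#' Generate a labeled synthetic WIP dataset
#'
#' Renders the requested number of specimens per template, writes each as an
#' 8-bit RGB PNG and returns (and writes) the manifest.  Per-record seeds are
#' derived from the master seed by a counter-based scheme, so each record's
#' image depends only on (template, sex, counter, master seed) -- never on
#' generation order -- and the whole dataset is reproducible byte-for-byte.
#'
#' @param templates list of [SpeciesTemplate-class] objects with unique ids.
#' @param counts named integer vector of image counts per template id (>= 0);
#'   defaults to the \code{counts} attribute of \code{templates}.
#' @param sexRatio fraction of female specimens per class (default 0.5).
#' @param optics an [OpticalConfig-class].
#' @param seed master integer seed.
#' @param outputDir directory for images and \code{manifest.csv}.
#' @param imageSize integer (H, W) of rendered images.
#' @param postprocess apply [acquisitionAdjust()] to written images (default
#'   TRUE, matching the photographic post-processing of the real database).
#' @return a [WingManifest-class] (also written to
#'   \code{outputDir/manifest.csv}).
#' @examples
#' \donttest{
#' tpl <- wellSeparatedTemplates(2)
#' mf <- generateDataset(tpl, counts = c(synth01 = 3, synth02 = 3),
#'                       seed = 1, outputDir = tempfile(),
#'                       imageSize = c(58, 128))
#' }
#' @export
generateDataset <- function(templates, counts = attr(templates, "counts"),
                            sexRatio = 0.5, optics = opticalConfig(),
                            seed = 0L, outputDir,
                            imageSize = c(116L, 256L), postprocess = TRUE) {
  ids <- vapply(templates, function(t) t@template_id, character(1))
  if (anyDuplicated(ids)) stop("template ids must be unique")
  if (is.null(counts)) stop("counts must be supplied (or attached to templates)")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.null(names(counts))) names(counts) <- ids
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outputDir)) stop("cannot create output directory: ", outputDir)
  rows <- list()
  counter <- 0L
  for (t in templates) {
    n <- counts[[t@template_id]]
    if (is.null(n) || n == 0) { next }
    nFemale <- round(n * sexRatio)
    for (i in seq_len(n)) {
      counter <- counter + 1L
      rs <- recordSeed(seed, counter)
      sex <- if (i <= nFemale) "female" else "male"
      tm <- generateThicknessMap(t, sex, imageSize, seed = rs)
      rw <- renderWing(tm, optics, genus = t@genus, complex = t@complex,
                       species = t@species, subspecies = t@subspecies,
                       sex = sex, seed = rs, templateId = t@template_id)
      img <- if (postprocess) acquisitionAdjust(rw@image) else rw@image
      id <- sprintf("%s_%04d", t@template_id, i)
      fn <- paste0(id, ".png")
      png::writePNG(img, file.path(outputDir, fn))
      rows[[counter]] <- data.frame(
        id = id, path = fn, genus = t@genus, complex = t@complex,
        species = t@species, subspecies = t@subspecies, sex = sex,
        source = "synthetic", seed = rs, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), path = character(), genus = character(),
               complex = character(), species = character(),
               subspecies = character(), sex = character(),
               source = character(), seed = integer(),
               stringsAsFactors = FALSE)
  df$path <- file.path(outputDir, df$path)
  mf <- wingManifest(df)
  out <- mf
  writeManifest(mf, file.path(outputDir, "manifest.csv"))
  out
}

#' Load a manifest's images
#'
#' Reads every record's PNG and returns a list of H x W x 3 arrays in
#' \[0, 1\], in record order.
#'
#' @param manifest a [WingManifest-class].
#' @return list of image arrays, named by record id.
#' @export
loadImages <- function(manifest) {
  recs <- manifest@records
  out <- lapply(recs$path, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  names(out) <- recs$id
  out
}
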
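## Species templates: the parametric recipes behind the synthetic database.

#' Construct a species template
#'
#' @param templateId unique identifier.
#' @param genus,complex,species,subspecies taxonomic label fields
#'   (\code{complex}/\code{subspecies} may be \code{NA}).
#' @param baseThickness membrane base thickness in nm.
#' @param patches data.frame with columns \code{u}, \code{v}, \code{radius},
#'   \code{delta} (relative centre, relative radius, nm offset); may be empty.
#' @param sexOffset nm added to male specimens.
#' @param noiseScale nm amplitude of the smooth per-specimen field.
#' @return a [SpeciesTemplate-class].
#' @export
speciesTemplate <- function(templateId, genus = "Glossina",
                            complex = NA_character_, species,
                            subspecies = NA_character_,
                            baseThickness = 250,
                            patches = data.frame(u = numeric(), v = numeric(),
                                                 radius = numeric(),
                                                 delta = numeric()),
                            sexOffset = 12, noiseScale = 10) {
  new("SpeciesTemplate", template_id = templateId, genus = genus,
      complex = as.character(complex), species = species,
      subspecies = as.character(subspecies),
      base_thickness = baseThickness, patches = patches,
      sex_offset = sexOffset, noise_scale = noiseScale)
}

setMethod("show", "SpeciesTemplate", function(object) {
  cat(sprintf(
    "SpeciesTemplate '%s': %s %s%s | base %.0f nm, %d patches, sex offset %.0f nm, noise %.0f nm\n",
    object@template_id, object@genus, object@species,
    if (!is.na(object@subspecies)) paste0(" ", object@subspecies) else "",
    object@base_thickness, nrow(object@patches), object@sex_offset,
    object@noise_scale))
})

#' Well-separated templates for capacity and recovery checks
#'
#' A fixed set of synthetic taxa whose base thicknesses and patch layouts are
#' spread widely across the first interference orders, so their rendered
#' colours are clearly distinct.  Used by the parameter-recovery evaluation
#' (cross-validated classification should recover the generating template
#' nearly perfectly).
#'
#' @param n number of templates (2--12).
#' @return list of [SpeciesTemplate-class] objects.
#' @export
wellSeparatedTemplates <- function(n = 8) {
  stopifnot(n >= 2, n <= 12)
  bases <- seq(150, 480, length.out = 12)[seq_len(n)]
  lapply(seq_len(n), function(i) {
    ui <- 0.15 + 0.7 * ((i * 0.618) %% 1)           # scattered patch centres
    vi <- 0.2 + 0.6 * ((i * 0.382) %% 1)
    patches <- data.frame(
      u = c(ui, 1 - ui),
      v = c(vi, 0.9 - vi / 2),
      radius = c(0.12, 0.18),
      delta = c(90 + 15 * i, -40 - 8 * i))
    speciesTemplate(
      templateId = sprintf("synth%02d", i),
      species = sprintf("synthetica%02d", i),
      baseThickness = bases[i], patches = patches,
      sexOffset = 10, noiseScale = 6)
  })
}

#' Non-Glossina negative template
#'
#' A template of another genus producing a noisy, weakly structured pattern:
#' the synthetic stand-in for the negative (non-Glossina insect) samples that
#' can be added to genus-level training.  Flows through the standard
#' generation and evaluation pipeline under its own genus label.
#'
#' @param templateId identifier (vary it to create several negative classes).
#' @return a [SpeciesTemplate-class] with genus "Insecta".
#' @export
negativeTemplate <- function(templateId = "negative01") {
  speciesTemplate(templateId, genus = "Insecta", species = "negative",
                  baseThickness = 700,
                  patches = data.frame(u = c(0.3, 0.7), v = c(0.4, 0.6),
                                       radius = c(0.25, 0.25),
                                       delta = c(120, -120)),
                  sexOffset = 0, noiseScale = 140)
}

#' Glossina fixture template set
#'
#' The shipped 23-taxon template set emulating the class structure of the
#' reference tsetse WIP database: one template per named species or
#' subspecies, with the database's imbalanced per-class image counts (1 to
#' 620) attached as the \code{count} column.  Members of the fuscipes,
#' palpalis and morsitans species complexes carry their complex label.
#'
#' @param file optional path to a template-set TSV; defaults to the fixture
#'   shipped with the package.
#' @return list of [SpeciesTemplate-class] objects with an attached
#'   \code{counts} attribute (named integer vector).
#' @export
glossinaTemplates <- function(file = system.file("extdata",
                                                 "glossina_templates.tsv",
                                                 package = "wipid")) {
  readTemplateSet(file)
}

#' Read / write template sets
#'
#' Template sets are serialised as plain TSV so fixtures stay versionable:
#' one row per template, patches encoded as
#' \code{"u:v:radius:delta;u:v:radius:delta"}.
#'
#' @param file path to the TSV.
#' @return \code{readTemplateSet}: a list of templates with a \code{counts}
#'   attribute; \code{writeTemplateSet}: the file path, invisibly.
#' @export
readTemplateSet <- function(file) {
  if (!file.exists(file)) stop("template file not found: ", file)
  df <- utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("template_id", "genus", "complex", "species", "subspecies",
            "count", "base_thickness", "sex_offset", "noise_scale", "patches")
  if (!all(need %in% names(df)))
    stop("template file '", file, "' lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  tpls <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    patches <- .parsePatches(r$patches)
    speciesTemplate(r$template_id, genus = r$genus, complex = r$complex,
                    species = r$species, subspecies = r$subspecies,
                    baseThickness = r$base_thickness, patches = patches,
                    sexOffset = r$sex_offset, noiseScale = r$noise_scale)
  })
  counts <- as.integer(df$count)
  names(counts) <- df$template_id
  attr(tpls, "counts") <- counts
  tpls
}

#' @rdname readTemplateSet
#' @param templates list of templates.
#' @param counts named integer vector of per-template image counts.
#' @export
writeTemplateSet <- function(templates, counts, file) {
  rows <- lapply(templates, function(t) {
    data.frame(template_id = t@template_id, genus = t@genus,
               complex = t@complex, species = t@species,
               subspecies = t@subspecies,
               count = unname(counts[t@template_id]),
               base_thickness = t@base_thickness,
               sex_offset = t@sex_offset, noise_scale = t@noise_scale,
               patches = .encodePatches(t@patches),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

.encodePatches <- function(p) {
  if (!nrow(p)) return("")
  paste(apply(p, 1, function(r) paste(signif(r, 6), collapse = ":")),
        collapse = ";")
}

.parsePatches <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(u = numeric(), v = numeric(), radius = numeric(),
                      delta = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  data.frame(u = m[, 1], v = m[, 2], radius = m[, 3], delta = m[, 4])
}
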
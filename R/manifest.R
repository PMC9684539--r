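## Manifests and taxonomic labels.

#' Coarsen taxonomic labels to an evaluation level
#'
#' Maps four-level labels (genus, species complex, species, subspecies) to a
#' class name at the requested level.  At \code{"subspecies"} (the finest
#' level) the class is \code{species_subspecies} where a subspecies is
#' defined, else the species.  At \code{"complex"}, members of the three
#' studied complexes (fuscipes, palpalis, morsitans) map to their complex;
#' every other label maps to the explicit \code{"unassigned"} class -- never
#' silently dropped.  At \code{"genus"} the genus is returned.
#'
#' @param records data.frame with columns \code{genus}, \code{complex},
#'   \code{species}, \code{subspecies} (e.g. manifest records).
#' @param level "genus", "complex" or "subspecies".
#' @return character vector of class names, one per record.
#' @examples
#' df <- data.frame(genus = "Glossina", complex = "palpalis",
#'                  species = "palpalis", subspecies = "gambiensis")
#' coarsenLabel(df, "complex")   # "palpalis"
#' @export
coarsenLabel <- function(records, level = c("subspecies", "complex", "genus")) {
  level <- match.arg(level)
  if (level == "genus") return(as.character(records$genus))
  if (level == "complex") {
    cpx <- as.character(records$complex)
    sp <- as.character(records$species)
    out <- ifelse(!is.na(cpx) & nzchar(cpx), cpx,
           ifelse(sp %in% c("fuscipes", "palpalis", "morsitans"), sp,
                  "unassigned"))
    return(out)
  }
  ssp <- as.character(records$subspecies)
  sp <- as.character(records$species)
  ifelse(!is.na(ssp) & nzchar(ssp), paste(sp, ssp, sep = "_"), sp)
}

#' Construct a manifest
#'
#' @param records data.frame of image records (see [WingManifest-class]).
#' @param level taxonomic level the class index is built at.
#' @return a [WingManifest-class].
#' @export
wingManifest <- function(records, level = "subspecies") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  cls <- sort(unique(coarsenLabel(records, level)))
  idx <- seq_along(cls) - 1L
  names(idx) <- cls
  new("WingManifest", records = records, class_index = idx, level = level)
}

#' Per-record class names of a manifest
#'
#' @param object a [WingManifest-class].
#' @param level taxonomic level; defaults to the manifest's working level.
#' @return character vector, one class per record.
#' @export
manifestClasses <- function(object, level = object@level) {
  coarsenLabel(object@records, level)
}

#' @describeIn wingManifest the record data.frame.
#' @param object a \code{WingManifest}.
#' @export
manifestRecords <- function(object) object@records

#' @describeIn wingManifest the class -> index map (0-based, contiguous).
#' @export
classIndex <- function(object) object@class_index

setMethod("show", "WingManifest", function(object) {
  tab <- table(manifestClasses(object))
  cat(sprintf("WingManifest: %d records, %d classes at level '%s'\n",
              nrow(object@records), length(tab), object@level))
  if (length(tab))
    cat(sprintf("  class sizes: min %d, median %.0f, max %d\n",
                min(tab), stats::median(tab), max(tab)))
})

#' Read / write manifests as CSV
#'
#' The on-disk manifest has the header
#' \code{id,path,genus,complex,species,subspecies,sex,source,seed}.  Paths
#' are stored relative to the manifest's directory.
#'
#' @param file CSV path.
#' @param level taxonomic level for the class index.
#' @param checkPaths verify that every image file exists (default TRUE on
#'   read).
#' @return \code{readManifest}: a [WingManifest-class];
#'   \code{writeManifest}: the file path, invisibly.
#' @export
readManifest <- function(file, level = "subspecies", checkPaths = TRUE) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "NA")
  root <- dirname(file)
  df$path <- ifelse(grepl("^/", df$path), df$path, file.path(root, df$path))
  if (checkPaths && nrow(df)) {
    miss <- !file.exists(df$path)
    if (any(miss))
      stop("manifest refers to missing image files, e.g. ", df$path[which(miss)[1]])
  }
  wingManifest(df, level = level)
}

#' @rdname readManifest
#' @param manifest a [WingManifest-class].
#' @export
writeManifest <- function(manifest, file) {
  df <- manifest@records
  root <- normalizePath(dirname(file), mustWork = FALSE)
  rel <- sub(paste0("^", root, "/"), "", normalizePath(df$path, mustWork = FALSE))
  df$path <- rel
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}
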
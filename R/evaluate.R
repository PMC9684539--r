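## Cross-validated evaluation at genus / species-complex / subspecies levels.

#' Classifier factories for cross-validation
#'
#' Thin wrappers giving the CNN and bag-of-features backends a common
#' \code{fit(images, labels, level)} interface for [runCV()].
#'
#' @param architecture architecture name or [ArchitectureSpec-class].
#' @param config a [TrainConfig-class].
#' @param augment augmentation argument list or NULL (see
#'   [trainWingClassifier()]).
#' @return a list with a \code{fit} function and a \code{name}.
#' @export
cnnClassifier <- function(architecture = "darknet9", config = trainConfig(),
                          augment = NULL) {
  force(architecture); force(config); force(augment)
  list(name = if (is.character(architecture)) architecture
              else architecture@name,
       fit = function(images, labels, level) {
         arch <- if (is.character(architecture))
           buildArchitecture(architecture, length(unique(labels)))
         else architecture
         trainWingClassifier(images, labels, arch, config, augment,
                             level = level)
       })
}

#' @rdname cnnClassifier
#' @param k,degree,cost,seed bag-of-features hyper-parameters (see
#'   [trainBofClassifier()]).
#' @export
bofClassifier <- function(k = 4000L, degree = 3, cost = 1, seed = 0L) {
  force(k); force(degree); force(cost); force(seed)
  list(name = "bof",
       fit = function(images, labels, level)
         trainBofClassifier(images, labels, k = k, degree = degree,
                            cost = cost, seed = seed, level = level))
}

#' Run k-fold cross-validation
#'
#' Trains one model per fold on the other k-1 folds and scores each record
#' exactly once with the model that never saw it.  Records of classes absent
#' from a fold's training data are still scored (and necessarily counted as
#' errors), mirroring how rare taxa fail in practice.
#'
#' @param manifest a [WingManifest-class].
#' @param folds a [FoldAssignment-class] consistent with the manifest.
#' @param classifier a factory from [cnnClassifier()] or [bofClassifier()].
#' @param level taxonomic level to train at (default the finest:
#'   subspecies where defined, species otherwise).
#' @param images optional pre-loaded image list (record order); loaded from
#'   the manifest when NULL.
#' @param verbose print per-fold progress.
#' @return a [PredictionSet-class].
#' @export
runCV <- function(manifest, folds, classifier, level = "subspecies",
                  images = NULL, verbose = FALSE) {
  stopifnot(is(manifest, "WingManifest"), is(folds, "FoldAssignment"))
  recs <- manifest@records
  if (!setequal(names(folds@assignment), recs$id))
    stop("fold assignment does not match the manifest records")
  if (is.null(images)) images <- loadImages(manifest)
  fvec <- folds@assignment[recs$id]
  labels <- coarsenLabel(recs, level)
  rows <- vector("list", folds@k)
  for (f in seq_len(folds@k) - 1L) {
    tr <- which(fvec != f); te <- which(fvec == f)
    if (!length(te)) next
    missing <- setdiff(unique(labels[te]), unique(labels[tr]))
    if (length(missing) && verbose)
      message("fold ", f, ": classes absent from training: ",
              paste(missing, collapse = ", "), " (scored as errors)")
    model <- classifier$fit(images[tr], labels[tr], level)
    pred <- predictWing(model, images[te])
    rows[[f + 1L]] <- data.frame(
      id = recs$id[te], genus = recs$genus[te], complex = recs$complex[te],
      species = recs$species[te], subspecies = recs$subspecies[te],
      true = labels[te], pred = as.character(pred), fold = f,
      max_prob = attr(pred, "prob"), stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d: accuracy %.3f", f,
                      mean(rows[[f + 1L]]$true == rows[[f + 1L]]$pred)))
  }
  new("PredictionSet", predictions = do.call(rbind, rows), level = level)
}

#' @describeIn runCV prediction data.frame accessor.
#' @param object a \code{PredictionSet}.
#' @export
cvPredictions <- function(object) object@predictions

setMethod("show", "PredictionSet", function(object) {
  p <- object@predictions
  cat(sprintf("PredictionSet: %d records, level '%s', mean accuracy %.3f\n",
              nrow(p), object@level, mean(p$true == p$pred)))
  pf <- vapply(split(p, p$fold), function(d) mean(d$true == d$pred),
               numeric(1))
  cat("  per-fold accuracy:", paste(sprintf("%.3f", pf), collapse = ", "), "\n")
})

## Label fields for every class seen in a prediction set (each class appears
## as a true label somewhere across the folds of a full CV).
.classFieldTable <- function(pred) {
  p <- pred@predictions
  unique(p[, c("true", "genus", "complex", "species", "subspecies")])
}

## Coarsen a vector of training-level class names via the field table.
.coarsenClasses <- function(classes, pred, level) {
  if (level == pred@level) return(classes)
  tab <- .classFieldTable(pred)
  i <- match(classes, tab$true)
  if (anyNA(i)) {
    ## an unseen predicted class (cannot happen in a full CV) maps by name
    out <- rep(NA_character_, length(classes))
    out[!is.na(i)] <- coarsenLabel(tab[i[!is.na(i)], ], level)
    out[is.na(i)] <- classes[is.na(i)]
    return(out)
  }
  coarsenLabel(tab[i, ], level)
}

#' Confusion matrix at a taxonomic level
#'
#' Coarsens both true and predicted classes to the requested level and
#' tabulates them; rows are true classes, columns predicted.
#'
#' @param pred a [PredictionSet-class].
#' @param level "genus", "complex" or "subspecies".
#' @return a [ConfusionMatrix-class].
#' @export
confusionWip <- function(pred, level = pred@level) {
  p <- pred@predictions
  truth <- coarsenLabel(p, level)
  predicted <- .coarsenClasses(p$pred, pred, level)
  classes <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, classes), factor(predicted, classes))
  new("ConfusionMatrix", level = level, classes = classes,
      counts = unclass(unname(counts)))
}

#' Accuracy of a confusion matrix (trace / total)
#'
#' @param cm a [ConfusionMatrix-class].
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  sum(diag(cm@counts)) / sum(cm@counts)
}

#' Accuracy at a taxonomic level
#'
#' @param pred a [PredictionSet-class].
#' @param level evaluation level.
#' @param membersOnly at the complex level, restrict to records belonging to
#'   one of the three studied complexes (drop the "unassigned" class).
#' @return fraction in \[0, 1\].
#' @export
accuracyAtLevel <- function(pred, level = pred@level, membersOnly = FALSE) {
  p <- pred@predictions
  truth <- coarsenLabel(p, level)
  predicted <- .coarsenClasses(p$pred, pred, level)
  keep <- if (membersOnly && level == "complex") truth != "unassigned"
          else rep(TRUE, length(truth))
  mean(truth[keep] == predicted[keep])
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix at level '%s' (%d classes, %d records, accuracy %.3f)\n",
              object@level, length(object@classes), sum(object@counts),
              accuracy(object)))
  m <- object@counts
  dimnames(m) <- list(true = object@classes, predicted = object@classes)
  print(m)
})

#' Export a prediction set / confusion matrix as CSV
#'
#' @param pred a [PredictionSet-class].
#' @param file CSV path.
#' @export
writePredictions <- function(pred, file) {
  utils::write.csv(pred@predictions[, c("id", "true", "pred", "fold",
                                        "max_prob")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePredictions
#' @param cm a [ConfusionMatrix-class].
#' @export
writeConfusion <- function(cm, file) {
  m <- cm@counts
  dimnames(m) <- list(cm@classes, cm@classes)
  utils::write.csv(m, file, quote = FALSE)
  invisible(file)
}

#' Plain-text accuracy report across levels
#'
#' @param pred a [PredictionSet-class].
#' @param file optional path; when NULL the report is returned as a
#'   character vector.
#' @export
accuracyReport <- function(pred, file = NULL) {
  lines <- c(
    sprintf("records scored: %d", nrow(pred@predictions)),
    sprintf("training level: %s", pred@level),
    sprintf("accuracy genus: %.4f", accuracyAtLevel(pred, "genus")),
    sprintf("accuracy complex (members): %.4f",
            accuracyAtLevel(pred, "complex", membersOnly = TRUE)),
    sprintf("accuracy finest: %.4f", accuracyAtLevel(pred, "subspecies")))
  pf <- vapply(split(pred@predictions, pred@predictions$fold),
               function(d) mean(d$true == d$pred), numeric(1))
  lines <- c(lines, sprintf("fold %s accuracy: %.4f", names(pf), pf))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}
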
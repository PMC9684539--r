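#' @import methods
NULL

#' Optical configuration for thin-film rendering
#'
#' Holds the optical constants and sampling grid used by the wing renderer:
#' the refractive index of the wing membrane (chitin-like, ~1.5), the ambient
#' index, the illumination incidence angle, the wavelength grid and the
#' illuminant spectral power on that grid.
#'
#' @slot film_refractive_index refractive index of the membrane (>= 1).
#' @slot ambient_refractive_index refractive index of the surrounding medium.
#' @slot incidence_angle illumination incidence, degrees from the normal.
#' @slot wavelength_grid strictly increasing wavelengths in nm, within
#'   \[380, 780\].
#' @slot illuminant relative spectral power at each grid point (>= 0, not all
#'   zero).
#' @export
setClass("OpticalConfig",
  representation(
    film_refractive_index = "numeric",
    ambient_refractive_index = "numeric",
    incidence_angle = "numeric",
    wavelength_grid = "numeric",
    illuminant = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (object@film_refractive_index < 1 || object@ambient_refractive_index < 1)
    msg <- c(msg, "refractive indices must be >= 1")
  wl <- object@wavelength_grid
  if (length(wl) < 2 || any(diff(wl) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(wl < 380 - 1e-9) || any(wl > 780 + 1e-9))
    msg <- c(msg, "wavelength grid must lie within [380, 780] nm")
  if (length(object@illuminant) != length(wl))
    msg <- c(msg, "illuminant must match the wavelength grid length")
  if (any(object@illuminant < 0) || all(object@illuminant == 0))
    msg <- c(msg, "illuminant must be >= 0 and not all zero")
  if (object@incidence_angle < 0 || object@incidence_angle >= 90)
    msg <- c(msg, "incidence angle must be in [0, 90) degrees")
  if (length(msg)) msg else TRUE
})

#' Species template for the synthetic wing generator
#'
#' A parametric description of the membrane-thickness field that produces one
#' taxon's wing interference pattern: a base thickness plus localised patches
#' of extra (or reduced) thickness, a small sex-dependent offset (faint sexual
#' dimorphism) and a per-specimen smooth noise amplitude.
#'
#' @slot template_id identifier, unique within a template set.
#' @slot genus,complex,species,subspecies taxonomic label fields;
#'   \code{complex} and \code{subspecies} may be \code{NA}.
#' @slot base_thickness membrane base thickness, nm (> 0).
#' @slot patches data.frame with columns \code{u}, \code{v} (centre in
#'   relative wing coordinates, \[0,1\]), \code{radius} (relative) and
#'   \code{delta} (thickness offset, nm).
#' @slot sex_offset thickness offset (nm) added for males.
#' @slot noise_scale amplitude (nm) of the smooth per-specimen random field.
#' @export
setClass("SpeciesTemplate",
  representation(
    template_id = "character",
    genus = "character",
    complex = "character",
    species = "character",
    subspecies = "character",
    base_thickness = "numeric",
    patches = "data.frame",
    sex_offset = "numeric",
    noise_scale = "numeric"
  )
)

setValidity("SpeciesTemplate", function(object) {
  msg <- character()
  if (!nzchar(object@template_id)) msg <- c(msg, "template_id must be non-empty")
  if (!nzchar(object@genus)) msg <- c(msg, "genus must be non-empty")
  if (object@base_thickness <= 0) msg <- c(msg, "base_thickness must be > 0")
  p <- object@patches
  if (nrow(p)) {
    if (!all(c("u", "v", "radius", "delta") %in% names(p)))
      msg <- c(msg, "patches need columns u, v, radius, delta")
    else if (any(p$u < 0) || any(p$u > 1) || any(p$v < 0) || any(p$v > 1))
      msg <- c(msg, "patch centres must lie in the unit wing region")
  }
  ## thickness must stay physical everywhere, three noise sigmas out
  deltas <- if (nrow(p)) p$delta else 0
  lo <- object@base_thickness + min(0, min(deltas)) + min(0, object@sex_offset) -
        3 * object@noise_scale
  hi <- object@base_thickness + max(0, sum(pmax(deltas, 0))) +
        max(0, object@sex_offset) + 3 * object@noise_scale
  if (lo < 50 || hi > 1500)
    msg <- c(msg, sprintf(
      "thickness range [%.0f, %.0f] nm leaves the physical band [50, 1500]",
      lo, hi))
  if (length(msg)) msg else TRUE
})

#' Per-pixel membrane thickness field
#'
#' The geometric substrate of one rendered wing: a thickness value per pixel,
#' the boolean wing mask, and named vein polylines (veins "V" and "VI" and the
#' trailing edge) used by the occlusion perturbations.
#'
#' @slot grid H x W matrix of thickness in nm (0 outside the mask).
#' @slot mask H x W logical matrix, TRUE inside the wing.
#' @slot veins named list of polylines (matrices with columns \code{x},
#'   \code{y} in pixel coordinates); includes \code{"V"}, \code{"VI"} and
#'   \code{"trailing_edge"}.
#' @export
setClass("ThicknessMap",
  representation(grid = "matrix", mask = "matrix", veins = "list")
)

setValidity("ThicknessMap", function(object) {
  msg <- character()
  if (!identical(dim(object@grid), dim(object@mask)))
    msg <- c(msg, "grid and mask dimensions differ")
  if (any(object@grid < 0)) msg <- c(msg, "thickness must be >= 0 everywhere")
  if (any(object@grid[!object@mask] != 0))
    msg <- c(msg, "thickness must be 0 outside the mask")
  bb <- which(object@mask, arr.ind = TRUE)
  if (nrow(bb)) {
    for (nm in names(object@veins)) {
      v <- object@veins[[nm]]
      if (any(v[, "x"] < min(bb[, 2]) - 1) || any(v[, "x"] > max(bb[, 2]) + 1) ||
          any(v[, "y"] < min(bb[, 1]) - 1) || any(v[, "y"] > max(bb[, 1]) + 1))
        msg <- c(msg, sprintf("vein '%s' leaves the mask bounding box", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic wing image
#'
#' @slot image H x W x 3 array, sRGB values in \[0, 1\].
#' @slot genus,complex,species,subspecies taxonomic label of the generating
#'   template.
#' @slot sex "male" or "female".
#' @slot seed integer seed the specimen was generated with.
#' @slot template_id id of the generating template.
#' @export
setClass("RenderedWing",
  representation(
    image = "array", genus = "character", complex = "character",
    species = "character", subspecies = "character", sex = "character",
    seed = "integer", template_id = "character"
  )
)

setValidity("RenderedWing", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) msg <- c(msg, "image must be H x W x 3")
  if (any(object@image < 0) || any(object@image > 1))
    msg <- c(msg, "channel values must lie in [0, 1]")
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(msg)) msg else TRUE
})

#' Labeled image manifest
#'
#' The record collection flowing through filtering, fold assignment, training
#' and evaluation.  Records carry a four-level taxonomic label (genus,
#' species complex, species, subspecies), sex and provenance.
#'
#' @slot records data.frame with columns \code{id}, \code{path}, \code{genus},
#'   \code{complex}, \code{species}, \code{subspecies}, \code{sex},
#'   \code{source}, \code{seed}.
#' @slot class_index named integer vector mapping each class name at the
#'   manifest's working level to a contiguous 0-based index.
#' @slot level taxonomic level the class index is built at (default the
#'   finest available label).
#' @export
setClass("WingManifest",
  representation(records = "data.frame", class_index = "integer",
                 level = "character")
)

setValidity("WingManifest", function(object) {
  msg <- character()
  need <- c("id", "path", "genus", "complex", "species", "subspecies",
            "sex", "source", "seed")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$id))
      msg <- c(msg, "record ids must be unique")
    present <- sort(unique(manifestClasses(object)))
    idx <- object@class_index
    if (length(idx) && (!setequal(names(idx), present) ||
        !identical(sort(unname(idx)), seq_along(idx) - 1L)))
      msg <- c(msg, "class_index must cover exactly the classes present, 0-based contiguous")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation fold assignment
#'
#' @slot k number of folds.
#' @slot assignment named integer vector, record id -> fold in 0..k-1.
#' @export
setClass("FoldAssignment",
  representation(k = "integer", assignment = "integer")
)

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  a <- object@assignment
  if (length(a) && (any(a < 0) || any(a >= object@k)))
    msg <- c(msg, "folds must lie in 0..k-1")
  if (is.null(names(a)) && length(a))
    msg <- c(msg, "assignment must be named by record id")
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration
#'
#' @slot width,height target size in pixels (default 256 x 116).
#' @slot value_range numeric length-2, the normalised intensity range.
#' @export
setClass("PreprocessConfig",
  representation(width = "integer", height = "integer", value_range = "numeric")
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "width and height must be positive")
  if (length(object@value_range) != 2 ||
      object@value_range[1] >= object@value_range[2])
    msg <- c(msg, "value_range must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

#' Declarative network architecture
#'
#' An ordered list of layer descriptors plus input geometry and class count.
#' Supports structural assertions (e.g. convolution-layer counts) and drives
#' the in-package training engine.
#'
#' @slot name one of "reduced_mobilenet", "darknet9", "darknet14", "resnet18".
#' @slot layers ordered list of layer descriptors (lists with at least
#'   \code{op}; weighted ops carry \code{filters}, \code{kernel},
#'   \code{stride}).
#' @slot input_size integer (H, W).
#' @slot num_classes integer >= 2.
#' @export
setClass("ArchitectureSpec",
  representation(name = "character", layers = "list",
                 input_size = "integer", num_classes = "integer")
)

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  ops <- vapply(object@layers, function(l) l$op, character(1))
  if (length(ops) < 2 || ops[length(ops)] != "softmax")
    msg <- c(msg, "architecture must end with softmax")
  roles <- vapply(object@layers, function(l)
    if (is.null(l$role)) "feature" else l$role, character(1))
  if (!any(roles == "classifier"))
    msg <- c(msg, "architecture must contain a classification layer")
  if (object@num_classes < 2) msg <- c(msg, "num_classes must be >= 2")
  for (l in object@layers) {
    if (l$op %in% c("conv", "depthwise_conv", "pointwise_conv") &&
        l$kernel %% 2 == 0)
      msg <- c(msg, "conv kernels must be odd")
    if (l$op %in% c("conv", "depthwise_conv", "pointwise_conv",
                    "fully_connected") && l$filters <= 0)
      msg <- c(msg, "filters/units must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' @slot epochs,batch_size positive integers.
#' @slot learning_rate step size (>= 0; 0 freezes the weights).
#' @slot seed integer RNG seed.
#' @slot loss fixed to "cross_entropy".
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batch_size = "integer",
                 learning_rate = "numeric", seed = "integer", loss = "character")
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs <= 0 || object@batch_size <= 0)
    msg <- c(msg, "epochs and batch_size must be positive")
  if (object@learning_rate < 0) msg <- c(msg, "learning_rate must be >= 0")
  if (!identical(object@loss, "cross_entropy"))
    msg <- c(msg, "loss is fixed to cross_entropy")
  if (length(msg)) msg else TRUE
})

#' Visual-word codebook for the bag-of-features baseline
#'
#' @slot centers k x d matrix of descriptor-space centroids.
#' @slot seed seed the dictionary was learned with.
#' @export
setClass("Codebook", representation(centers = "matrix", seed = "integer"))

setValidity("Codebook", function(object) {
  if (!all(is.finite(object@centers))) "centers must be finite" else TRUE
})

#' Cross-validated predictions
#'
#' One row per scored record: true label fields, the predicted class at the
#' training level, the fold whose held-out model scored it, and the maximum
#' class probability.
#'
#' @slot predictions data.frame with columns \code{id}, \code{genus},
#'   \code{complex}, \code{species}, \code{subspecies}, \code{true},
#'   \code{pred}, \code{fold}, \code{max_prob}.
#' @slot level taxonomic level the classifier was trained at.
#' @export
setClass("PredictionSet",
  representation(predictions = "data.frame", level = "character")
)

setValidity("PredictionSet", function(object) {
  need <- c("id", "genus", "complex", "species", "subspecies",
            "true", "pred", "fold", "max_prob")
  if (!all(need %in% names(object@predictions)))
    return(paste("predictions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@predictions$id))
    return("every record must be predicted exactly once")
  TRUE
})

#' Square confusion matrix at a taxonomic level
#'
#' @slot level "genus", "complex" or "subspecies" (finest).
#' @slot classes ordered class names.
#' @slot counts square count matrix, rows = true, columns = predicted.
#' @export
setClass("ConfusionMatrix",
  representation(level = "character", classes = "character", counts = "matrix")
)

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (d[1] != d[2] || d[1] != length(object@classes))
    msg <- c(msg, "counts must be square with one row per class")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One robustness-grid condition
#'
#' @slot kind one of the 15 enumerated perturbation kinds.
#' @slot params named list of kind-specific parameters (sigma, probability,
#'   noise sd, seed, ...).
#' @export
setClass("TransformSpec", representation(kind = "character", params = "list"))

.TRANSFORM_KINDS <- c("none", "gaussian_blur", "lens_blur", "video_distortion",
                      "spread", "hurl", "rgb_noise", "cie_noise",
                      "occlude_trailing_edge", "occlude_outer_vein_V",
                      "occlude_inner_vein_VI", "raw_unprocessed",
                      "flip_h", "flip_v", "raw_resized")

setValidity("TransformSpec", function(object) {
  msg <- character()
  if (!object@kind %in% .TRANSFORM_KINDS)
    msg <- c(msg, paste("unknown transform kind:", object@kind))
  p <- object@params
  if (!is.null(p$probability) && (p$probability < 0 || p$probability > 1))
    msg <- c(msg, "probability must lie in [0, 1]")
  if (!is.null(p$sigma) && p$sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Robustness evaluation report
#'
#' @slot grid species x condition matrix of identification accuracies
#'   (NA where no samples).
#' @slot lights same shape, traffic-light codes: "green" (accuracy 1),
#'   "yellow" (0 < accuracy < 1), "red" (accuracy 0), "blank" (no samples).
#' @export
setClass("RobustnessReport",
  representation(grid = "matrix", lights = "matrix")
)

setValidity("RobustnessReport", function(object) {
  g <- object@grid; l <- object@lights
  if (!identical(dim(g), dim(l))) return("grid and lights dimensions differ")
  expect <- ifelse(is.na(g), "blank",
            ifelse(g == 1, "green", ifelse(g == 0, "red", "yellow")))
  if (!identical(unname(expect), unname(l)))
    return("lights inconsistent with the accuracy grid")
  TRUE
})

#' A trained wing classifier
#'
#' Common wrapper for the CNN and bag-of-features backends: both expose
#' \code{predictWing()} over preprocessed images.
#'
#' @slot backend "cnn" or "bof".
#' @slot model backend-specific fitted state.
#' @slot classes class names in training order.
#' @slot level taxonomic level trained at.
#' @export
setClass("WingClassifier",
  representation(backend = "character", model = "list",
                 classes = "character", level = "character")
)
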
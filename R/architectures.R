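## Declarative architecture specifications.
##
## Four classifiers are supported: two truncations of the DarkNet-19
## backbone (DarkNet-9: 8 convolution layers + 1 classification layer;
## DarkNet-14: 13 + 1), a reduced MobileNet (no 1024-filter scale, one
## depthwise convolution per scale, two fully connected head layers, batch
## normalisation throughout) and the published ResNet-18 layout trained from
## random initialisation.

.layer <- function(op, filters = 0L, kernel = 0L, stride = 1L,
                   role = "feature", act = "relu", pad = NULL,
                   downsample = FALSE) {
  l <- list(op = op, filters = as.integer(filters), kernel = as.integer(kernel),
            stride = as.integer(stride), role = role, act = act,
            downsample = downsample)
  if (!is.null(pad)) l$pad <- as.integer(pad)
  l
}

.convBlock <- function(filters, kernel, act, stride = 1L) {
  list(.layer("conv", filters, kernel, stride, act = act),
       .layer("batch_norm"),
       .layer("activation", act = act))
}

.darknetLayers <- function(numClasses, scales) {
  act <- "leaky"
  ls <- c(.convBlock(32, 3, act), list(.layer("maxpool", kernel = 2, stride = 2)),
          .convBlock(64, 3, act), list(.layer("maxpool", kernel = 2, stride = 2)),
          .convBlock(128, 3, act), .convBlock(64, 1, act), .convBlock(128, 3, act),
          list(.layer("maxpool", kernel = 2, stride = 2)),
          .convBlock(256, 3, act), .convBlock(128, 1, act), .convBlock(256, 3, act))
  if (scales >= 4) {
    ls <- c(ls, list(.layer("maxpool", kernel = 2, stride = 2)),
            .convBlock(512, 3, act), .convBlock(256, 1, act),
            .convBlock(512, 3, act), .convBlock(256, 1, act),
            .convBlock(512, 3, act))
  }
  c(ls, list(.layer("conv", numClasses, 1, role = "classifier"),
             .layer("global_avg_pool"),
             .layer("softmax")))
}

.mobilenetLayers <- function(numClasses) {
  ls <- c(.convBlock(32, 3, "relu", stride = 2))
  inch <- 32L
  for (f in c(64, 128, 256, 512)) {
    ls <- c(ls,
            list(.layer("depthwise_conv", inch, kernel = 3, stride = 2)),
            list(.layer("batch_norm"), .layer("activation")),
            list(.layer("pointwise_conv", f, 1)),
            list(.layer("batch_norm"), .layer("activation")))
    inch <- as.integer(f)
  }
  c(ls, list(.layer("global_avg_pool"),
             .layer("fully_connected", 512),
             .layer("batch_norm"), .layer("activation"),
             .layer("fully_connected", numClasses, role = "classifier"),
             .layer("softmax")))
}

.resnet18Layers <- function(numClasses) {
  ls <- list(.layer("conv", 64, 7, stride = 2),
             .layer("batch_norm"), .layer("activation"),
             .layer("maxpool", kernel = 3, stride = 2, pad = 1))
  stages <- list(c(64, 1), c(64, 1), c(128, 2), c(128, 1),
                 c(256, 2), c(256, 1), c(512, 2), c(512, 1))
  for (s in stages)
    ls <- c(ls, list(.layer("residual_block", s[1], 3, stride = s[2],
                            downsample = s[2] > 1)))
  c(ls, list(.layer("global_avg_pool"),
             .layer("fully_connected", numClasses, role = "classifier"),
             .layer("softmax")))
}

#' Build a network architecture
#'
#' Returns the declarative layer specification of one of the four supported
#' classifiers.  All architectures end in a classification stage followed by
#' softmax and accept any input size large enough for their downsampling
#' chain (256 x 256 by default).
#'
#' @param name "darknet9", "darknet14", "reduced_mobilenet" or "resnet18".
#' @param numClasses number of output classes (>= 2).
#' @param inputSize integer (H, W), default c(256, 256).
#' @return an [ArchitectureSpec-class].
#' @examples
#' countConvLayers(buildArchitecture("darknet9", 5))    # 8
#' countConvLayers(buildArchitecture("darknet14", 5))   # 13
#' @export
buildArchitecture <- function(name = c("darknet9", "darknet14",
                                       "reduced_mobilenet", "resnet18"),
                              numClasses, inputSize = c(256L, 256L)) {
  name <- match.arg(name)
  if (numClasses < 2) stop("numClasses must be >= 2")
  layers <- switch(name,
    darknet9 = .darknetLayers(numClasses, scales = 3),
    darknet14 = .darknetLayers(numClasses, scales = 4),
    reduced_mobilenet = .mobilenetLayers(numClasses),
    resnet18 = .resnet18Layers(numClasses))
  new("ArchitectureSpec", name = name, layers = layers,
      input_size = as.integer(inputSize), num_classes = as.integer(numClasses))
}

#' Count convolution layers of an architecture
#'
#' Counts conv, depthwise and pointwise convolution descriptors (residual
#' blocks contribute their two main convolutions), excluding the final
#' classification layer and projection shortcuts.
#'
#' @param spec an [ArchitectureSpec-class].
#' @return integer count.
#' @export
countConvLayers <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  n <- 0L
  for (l in spec@layers) {
    if (l$op %in% c("conv", "depthwise_conv", "pointwise_conv") &&
        l$role != "classifier") n <- n + 1L
    if (l$op == "residual_block") n <- n + 2L
  }
  n
}

#' Count trainable parameters
#'
#' Instantiates the architecture's weights and counts them (convolution and
#' fully connected weights and biases, batch-norm scales and shifts).
#'
#' @param spec an [ArchitectureSpec-class].
#' @return integer parameter count.
#' @export
countParameters <- function(spec) {
  net <- withSeed(0L, initNetwork(spec))
  total <- 0
  addP <- function(st) {
    for (nm in intersect(names(st), c("W", "b", "gamma", "beta")))
      total <<- total + length(st[[nm]])
    for (sub in st$sub) addP(sub)
  }
  for (st in net$layers) addP(st)
  as.integer(total)
}

#' Maximum convolutional filter count in a spec
#'
#' @param spec an [ArchitectureSpec-class].
#' @param excludeClassifier drop the classification layer (default TRUE).
#' @return integer.
#' @export
maxFilterCount <- function(spec, excludeClassifier = TRUE) {
  f <- vapply(spec@layers, function(l) {
    if (excludeClassifier && l$role == "classifier") return(0L)
    if (l$op %in% c("conv", "pointwise_conv", "residual_block",
                    "fully_connected")) l$filters else 0L
  }, integer(1))
  max(f)
}

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec '%s': %d layer descriptors, %d conv layers + 1 classification layer\n",
              object@name, length(object@layers), countConvLayers(object)))
  cat(sprintf("  input %d x %d x 3 -> %d classes\n",
              object@input_size[1], object@input_size[2], object@num_classes))
})
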
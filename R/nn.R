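## Convolutional training engine.
##
## Activations live as C x (H*W*N) matrices (pixel-major within an image,
## image-major across the batch); convolution is im2col (compiled) followed
## by a BLAS GEMM; gradients flow back through col2im.  Batch normalisation
## keeps exponential running statistics for inference.  Optimisation is Adam
## with cross-entropy loss.  Everything is seeded through R's RNG, so
## training is deterministic for a fixed (data, config, seed).

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

## ---- initialisation ------------------------------------------------------

.initLayerState <- function(l, C) {
  ## returns list(state, outChannels); spatial bookkeeping happens at run time
  he <- function(fanIn, n) stats::rnorm(n, sd = sqrt(2 / fanIn))
  st <- list(desc = l)
  outC <- C
  if (l$op == "conv") {
    k <- l$kernel
    st$W <- matrix(he(k * k * C, l$filters * k * k * C), nrow = l$filters)
    st$b <- numeric(l$filters)
    st$inC <- C; outC <- l$filters
  } else if (l$op == "pointwise_conv") {
    st$W <- matrix(he(C, l$filters * C), nrow = l$filters)
    st$b <- numeric(l$filters)
    st$inC <- C; outC <- l$filters
  } else if (l$op == "depthwise_conv") {
    k <- l$kernel
    st$W <- matrix(he(k * k, C * k * k), nrow = C)   # one k x k kernel per channel
    st$b <- numeric(C)
    st$inC <- C; outC <- C
  } else if (l$op == "batch_norm") {
    st$gamma <- rep(1, C); st$beta <- numeric(C)
    st$run_mean <- numeric(C); st$run_var <- rep(1, C)
  } else if (l$op == "fully_connected") {
    st$W <- matrix(he(C, l$filters * C), nrow = l$filters)
    st$b <- numeric(l$filters)
    st$inC <- C; outC <- l$filters
  } else if (l$op == "residual_block") {
    f <- l$filters
    sub <- list()
    sub$conv1 <- .initLayerState(.layer("conv", f, 3, l$stride), C)$state
    sub$bn1 <- .initLayerState(.layer("batch_norm"), f)$state
    sub$conv2 <- .initLayerState(.layer("conv", f, 3, 1), f)$state
    sub$bn2 <- .initLayerState(.layer("batch_norm"), f)$state
    if (l$stride > 1 || C != f) {
      sub$proj <- .initLayerState(.layer("conv", f, 1, l$stride), C)$state
      sub$bnp <- .initLayerState(.layer("batch_norm"), f)$state
    }
    st$sub <- sub
    outC <- f
  }
  list(state = st, outChannels = outC)
}

## Instantiate weights for an ArchitectureSpec (RNG-dependent; seed outside).
initNetwork <- function(spec) {
  C <- 3L
  layers <- vector("list", length(spec@layers))
  for (i in seq_along(spec@layers)) {
    r <- .initLayerState(spec@layers[[i]], C)
    layers[[i]] <- r$state
    C <- r$outChannels
  }
  list(spec = spec, layers = layers)
}

## ---- primitive forward / backward ---------------------------------------

.convPad <- function(l) if (!is.null(l$pad)) l$pad else l$kernel %/% 2L

.fwdConv <- function(st, act, keep) {
  l <- st$desc
  k <- max(l$kernel, 1L); p <- .convPad(l); s <- l$stride
  if (k == 1 && s == 1) {
    out <- st$W %*% act$A + st$b
    cache <- if (keep) list(X = act$A, pw = TRUE, dims = act[c("H", "W", "N")])
  } else {
    cols <- im2col_cpp(act$A, act$H, act$W, act$N, k, k, s, p)
    out <- st$W %*% cols + st$b
    cache <- if (keep) list(cols = cols, pw = FALSE,
                            dims = act[c("H", "W", "N")], k = k, s = s, p = p)
  }
  Ho <- (act$H + 2 * .convPad(l) - k) %/% s + 1L
  Wo <- (act$W + 2 * .convPad(l) - k) %/% s + 1L
  list(act = list(A = out, H = Ho, W = Wo, N = act$N), cache = cache)
}

.bwdConv <- function(st, cache, dOut) {
  if (isTRUE(cache$pw)) {
    grads <- list(W = dOut %*% t(cache$X), b = rowSums(dOut))
    dA <- crossprod(st$W, dOut)
  } else {
    grads <- list(W = dOut %*% t(cache$cols), b = rowSums(dOut))
    dcols <- crossprod(st$W, dOut)
    d <- cache$dims
    dA <- col2im_cpp(dcols, st$inC, d$H, d$W, d$N, cache$k, cache$k,
                     cache$s, cache$p)
  }
  list(dA = dA, grads = grads)
}

.fwdDepthwise <- function(st, act, keep) {
  l <- st$desc
  k <- l$kernel; p <- .convPad(l); s <- l$stride
  C <- nrow(act$A)
  cols <- im2col_cpp(act$A, act$H, act$W, act$N, k, k, s, p)
  L <- ncol(cols); k2 <- k * k
  colsA <- cols; dim(colsA) <- c(k2, C, L)
  out <- colSums(colsA * as.vector(t(st$W)), dims = 1) + st$b
  Ho <- (act$H + 2 * p - k) %/% s + 1L
  Wo <- (act$W + 2 * p - k) %/% s + 1L
  cache <- if (keep) list(colsA = colsA, dims = act[c("H", "W", "N")],
                          k = k, s = s, p = p)
  list(act = list(A = out, H = Ho, W = Wo, N = act$N), cache = cache)
}

.bwdDepthwise <- function(st, cache, dOut) {
  k2 <- cache$k^2
  C <- nrow(dOut); L <- ncol(dOut)
  dOutExp <- rep(dOut, each = k2)          # k2 x C x L expansion
  dim(dOutExp) <- c(k2, C, L)
  dWt <- rowSums(cache$colsA * dOutExp, dims = 2)    # k2 x C
  dcolsA <- dOutExp * as.vector(t(st$W))
  dim(dcolsA) <- c(k2 * C, L)
  d <- cache$dims
  dA <- col2im_cpp(dcolsA, C, d$H, d$W, d$N, cache$k, cache$k,
                   cache$s, cache$p)
  list(dA = dA, grads = list(W = t(dWt), b = rowSums(dOut)))
}

.fwdBN <- function(st, act, train, keep) {
  A <- act$A
  if (train) {
    mu <- rowMeans(A)
    v <- rowMeans(A * A) - mu^2
    st$run_mean <- .BN_MOMENTUM * st$run_mean + (1 - .BN_MOMENTUM) * mu
    st$run_var <- .BN_MOMENTUM * st$run_var + (1 - .BN_MOMENTUM) * v
  } else {
    mu <- st$run_mean; v <- st$run_var
  }
  invstd <- 1 / sqrt(v + .BN_EPS)
  xhat <- (A - mu) * invstd
  out <- st$gamma * xhat + st$beta
  act$A <- out
  cache <- if (keep) list(xhat = xhat, invstd = invstd)
  list(act = act, cache = cache, state = st)
}

.bwdBN <- function(st, cache, dOut) {
  xhat <- cache$xhat
  grads <- list(gamma = rowSums(dOut * xhat), beta = rowSums(dOut))
  dxhat <- dOut * st$gamma
  dA <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dA = dA, grads = grads)
}

.fwdAct <- function(st, act, keep) {
  slope <- if (identical(st$desc$act, "leaky")) 0.1 else 0
  neg <- act$A < 0
  act$A[neg] <- act$A[neg] * slope
  list(act = act, cache = if (keep) list(neg = neg, slope = slope))
}

.bwdAct <- function(cache, dOut) {
  dOut[cache$neg] <- dOut[cache$neg] * cache$slope
  list(dA = dOut, grads = NULL)
}

.fwdMaxpool <- function(st, act, keep) {
  l <- st$desc
  p <- if (!is.null(l$pad)) l$pad else 0L
  r <- maxpool_cpp(act$A, act$H, act$W, act$N, l$kernel, l$stride, p)
  Ho <- (act$H + 2 * p - l$kernel) %/% l$stride + 1L
  Wo <- (act$W + 2 * p - l$kernel) %/% l$stride + 1L
  cache <- if (keep) list(argmax = r$argmax, ncolIn = ncol(act$A))
  list(act = list(A = r$out, H = Ho, W = Wo, N = act$N), cache = cache)
}

.fwdGAP <- function(act, keep) {
  HW <- act$H * act$W
  C <- nrow(act$A)
  out <- vapply(seq_len(act$N), function(n)
    rowMeans(act$A[, ((n - 1) * HW + 1):(n * HW), drop = FALSE]),
    numeric(C))
  if (C == 1) out <- matrix(out, nrow = 1)
  list(act = list(A = out, H = 1L, W = 1L, N = act$N),
       cache = if (keep) list(HW = HW, H = act$H, W = act$W))
}

.bwdGAP <- function(cache, dOut) {
  HW <- cache$HW
  dA <- dOut[, rep(seq_len(ncol(dOut)), each = HW), drop = FALSE] / HW
  list(dA = dA, grads = NULL)
}

## ---- network forward / backward -----------------------------------------

.residualForward <- function(st, act, train, keep) {
  sub <- st$sub
  caches <- list()
  r1 <- .fwdConv(sub$conv1, act, keep); caches$conv1 <- r1$cache
  rb1 <- .fwdBN(sub$bn1, r1$act, train, keep); caches$bn1 <- rb1$cache
  sub$bn1 <- rb1$state
  ra1 <- .fwdAct(list(desc = list(act = "relu")), rb1$act, keep)
  caches$act1 <- ra1$cache
  r2 <- .fwdConv(sub$conv2, ra1$act, keep); caches$conv2 <- r2$cache
  rb2 <- .fwdBN(sub$bn2, r2$act, train, keep); caches$bn2 <- rb2$cache
  sub$bn2 <- rb2$state
  if (!is.null(sub$proj)) {
    rp <- .fwdConv(sub$proj, act, keep); caches$proj <- rp$cache
    rbp <- .fwdBN(sub$bnp, rp$act, train, keep); caches$bnp <- rbp$cache
    sub$bnp <- rbp$state
    sc <- rbp$act$A
  } else sc <- act$A
  s <- rb2$act
  s$A <- s$A + sc
  neg <- s$A < 0
  s$A[neg] <- 0
  st$sub <- sub
  list(act = s, cache = if (keep) c(caches, list(neg = neg)), state = st)
}

.residualBackward <- function(st, cache, dOut) {
  sub <- st$sub
  dOut[cache$neg] <- 0
  grads <- list()
  ## main branch
  b2 <- .bwdBN(sub$bn2, cache$bn2, dOut); grads$bn2 <- b2$grads
  c2 <- .bwdConv(sub$conv2, cache$conv2, b2$dA); grads$conv2 <- c2$grads
  da1 <- .bwdAct(cache$act1, c2$dA)$dA
  b1 <- .bwdBN(sub$bn1, cache$bn1, da1); grads$bn1 <- b1$grads
  c1 <- .bwdConv(sub$conv1, cache$conv1, b1$dA); grads$conv1 <- c1$grads
  dA <- c1$dA
  ## shortcut branch
  if (!is.null(sub$proj)) {
    bp <- .bwdBN(sub$bnp, cache$bnp, dOut); grads$bnp <- bp$grads
    cp <- .bwdConv(sub$proj, cache$proj, bp$dA); grads$proj <- cp$grads
    dA <- dA + cp$dA
  } else dA <- dA + dOut
  list(dA = dA, grads = grads)
}

## Forward pass; keep = TRUE retains caches for backprop.
nnForward <- function(net, act, train = FALSE, keep = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    st <- net$layers[[i]]
    op <- st$desc$op
    r <- switch(op,
      conv = , pointwise_conv = .fwdConv(st, act, keep),
      depthwise_conv = .fwdDepthwise(st, act, keep),
      batch_norm = .fwdBN(st, act, train, keep),
      activation = .fwdAct(st, act, keep),
      maxpool = .fwdMaxpool(st, act, keep),
      global_avg_pool = .fwdGAP(act, keep),
      fully_connected = .fwdConv(st, act, keep),  # acts on C x N matrices
      residual_block = .residualForward(st, act, train, keep),
      softmax = {
        A <- act$A
        A <- sweep(A, 2, apply(A, 2, max), "-")
        E <- exp(A)
        act$A <- sweep(E, 2, colSums(E), "/")
        list(act = act, cache = NULL)
      },
      stop("unknown layer op: ", op))
    act <- r$act
    caches[[i]] <- r$cache
    if (!is.null(r$state)) net$layers[[i]] <- r$state
  }
  list(act = act, caches = caches, net = net)
}

## Backward from softmax/cross-entropy: dLogits = probs - onehot, averaged.
nnBackward <- function(net, caches, probs, labelIdx) {
  N <- ncol(probs)
  dA <- probs
  dA[cbind(labelIdx, seq_len(N))] <- dA[cbind(labelIdx, seq_len(N))] - 1
  dA <- dA / N
  gradsAll <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    st <- net$layers[[i]]
    op <- st$desc$op
    if (op == "softmax") next   # folded into the initial gradient
    r <- switch(op,
      conv = , pointwise_conv = , fully_connected =
        .bwdConv(st, caches[[i]], dA),
      depthwise_conv = .bwdDepthwise(st, caches[[i]], dA),
      batch_norm = .bwdBN(st, caches[[i]], dA),
      activation = .bwdAct(caches[[i]], dA),
      maxpool = list(dA = maxpool_back_cpp(dA, caches[[i]]$argmax,
                                           caches[[i]]$ncolIn), grads = NULL),
      global_avg_pool = .bwdGAP(caches[[i]], dA),
      residual_block = .residualBackward(st, caches[[i]], dA))
    dA <- r$dA
    gradsAll[i] <- list(r$grads)   # keep NULLs in place
  }
  gradsAll
}

## ---- Adam ----------------------------------------------------------------

.adamStep <- function(st, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(grads)) return(st)
  if (!is.null(st$sub)) {      # residual block: recurse into sublayers
    for (nm in names(grads))
      st$sub[[nm]] <- .adamStep(st$sub[[nm]], grads[[nm]], lr, t,
                                beta1, beta2, eps)
    return(st)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    mkey <- paste0(".m_", nm); vkey <- paste0(".v_", nm)
    m <- if (is.null(st[[mkey]])) g * 0 else st[[mkey]]
    v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    st[[nm]] <- st[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    st[[mkey]] <- m; st[[vkey]] <- v
  }
  st
}

## ---- data plumbing -------------------------------------------------------

## Stack a list of H x W x 3 images into the engine's C x (H*W*N) layout.
.stackImages <- function(images) {
  H <- dim(images[[1]])[1]; W <- dim(images[[1]])[2]
  N <- length(images)
  A <- matrix(0, 3, H * W * N)
  for (n in seq_len(N)) {
    img <- images[[n]]
    A[, ((n - 1) * H * W + 1):(n * H * W)] <-
      rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
            as.vector(img[, , 3]))
  }
  list(A = A, H = H, W = W, N = N)
}

## ---- public API ----------------------------------------------------------

#' Training configuration
#'
#' @param epochs passes over the training set.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size (0 freezes the weights).
#' @param seed integer seed controlling initialisation and batch order.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L, learningRate = 1e-3,
                        seed = 0L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batch_size = as.integer(batchSize),
      learning_rate = learningRate, seed = as.integer(seed),
      loss = "cross_entropy")
}

#' Train a convolutional wing classifier
#'
#' Trains one of the supported architectures from random initialisation with
#' Adam and cross-entropy loss.  Images are resized to the architecture's
#' input size; optional augmentation (flips, rotation, zoom) is re-sampled
#' every epoch from seeds derived from the training seed, so the whole run
#' is deterministic.
#'
#' @param images list of H x W x 3 arrays in \[0, 1\].
#' @param labels character/factor vector of class labels (>= 2 classes).
#' @param architecture an [ArchitectureSpec-class] or an architecture name.
#' @param config a [TrainConfig-class].
#' @param augment NULL (off) or a list of arguments for [augmentImage()]
#'   (\code{flipH}, \code{flipV}, \code{maxRotation}, \code{zoomRange}).
#' @param level taxonomic level tag carried on the classifier.
#' @return a [WingClassifier-class] with the per-epoch loss trace in
#'   \code{model$trace}.
#' @export
trainWingClassifier <- function(images, labels, architecture = "darknet9",
                                config = trainConfig(), augment = NULL,
                                level = "subspecies") {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("training requires at least 2 classes, got ", length(classes))
  if (is.character(architecture))
    architecture <- buildArchitecture(architecture, length(classes))
  if (architecture@num_classes != length(classes))
    stop("architecture num_classes (", architecture@num_classes,
         ") != number of label classes (", length(classes), ")")
  h <- architecture@input_size[1]; w <- architecture@input_size[2]
  images <- lapply(images, .resizeBilinear, h = h, w = w)
  labelIdx <- match(labels, classes)
  n <- length(images)
  trace <- numeric(config@epochs)
  withSeed(config@seed, {
    net <- initNetwork(architecture)
    t <- 0
    for (ep in seq_len(config@epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config@batch_size)) {
        idx <- perm[start:min(start + config@batch_size - 1, n)]
        batch <- images[idx]
        if (!is.null(augment)) {
          batch <- lapply(seq_along(idx), function(j)
            do.call(augmentImage,
                    c(list(image = batch[[j]],
                           seed = recordSeed(config@seed,
                                             ep * 100000 + idx[j])),
                      augment)))
        }
        act <- .stackImages(batch)
        fw <- nnForward(net, act, train = TRUE, keep = TRUE)
        net <- fw$net
        probs <- fw$act$A
        li <- labelIdx[idx]
        losses <- c(losses,
                    -mean(log(pmax(probs[cbind(li, seq_along(li))], 1e-12))))
        grads <- nnBackward(net, fw$caches, probs, li)
        t <- t + 1
        for (i in seq_along(net$layers))
          net$layers[[i]] <- .adamStep(net$layers[[i]], grads[[i]],
                                       config@learning_rate, t)
      }
      trace[ep] <- mean(losses)
    }
    new("WingClassifier", backend = "cnn",
        model = list(net = net, trace = trace, config = config),
        classes = classes, level = level)
  })
}

#' Class probabilities for a batch of images
#'
#' Runs the classifier forward (inference mode: batch-norm uses running
#' statistics) and returns one probability row per image; rows are
#' nonnegative and sum to 1.
#'
#' @param classifier a [WingClassifier-class] (CNN or BoF backend).
#' @param images list of H x W x 3 arrays in \[0, 1\].
#' @return matrix (length(images) x classes) of probabilities.
#' @export
forwardProbs <- function(classifier, images) {
  stopifnot(is(classifier, "WingClassifier"))
  if (classifier@backend == "bof")
    return(.bofForwardProbs(classifier, images))
  if (classifier@backend == "custom") {
    p <- classifier@model$fn(images)
    colnames(p) <- classifier@classes
    return(p)
  }
  net <- classifier@model$net
  h <- net$spec@input_size[1]; w <- net$spec@input_size[2]
  images <- lapply(images, .resizeBilinear, h = h, w = w)
  ## batch in chunks to bound memory on large inputs
  out <- matrix(0, length(images), length(classifier@classes))
  for (start in seq(1, length(images), by = 32)) {
    idx <- start:min(start + 31, length(images))
    act <- .stackImages(images[idx])
    fw <- nnForward(net, act, train = FALSE, keep = FALSE)
    out[idx, ] <- t(fw$act$A)
  }
  colnames(out) <- classifier@classes
  out
}

#' Predict classes for a batch of images
#'
#' @param classifier a [WingClassifier-class].
#' @param images list of H x W x 3 arrays.
#' @return character vector of predicted class names with the maximum
#'   probability attached as attribute \code{"prob"}.
#' @export
predictWing <- function(classifier, images) {
  p <- forwardProbs(classifier, images)
  idx <- max.col(p, ties.method = "first")
  out <- classifier@classes[idx]
  attr(out, "prob") <- p[cbind(seq_len(nrow(p)), idx)]
  out
}

#' Per-epoch training loss trace
#'
#' @param classifier a trained [WingClassifier-class] (CNN backend).
#' @return numeric vector of mean cross-entropy per epoch.
#' @export
lossTrace <- function(classifier) {
  stopifnot(is(classifier, "WingClassifier"))
  classifier@model$trace
}

setMethod("show", "WingClassifier", function(object) {
  cat(sprintf("WingClassifier [%s] over %d classes at level '%s'\n",
              object@backend, length(object@classes), object@level))
  if (object@backend == "cnn" && length(object@model$trace))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                utils::tail(object@model$trace, 1),
                length(object@model$trace)))
})
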
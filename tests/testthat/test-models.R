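test_that("DarkNet truncations have the documented convolution counts", {
  expect_equal(countConvLayers(buildArchitecture("darknet9", 5)), 8)
  expect_equal(countConvLayers(buildArchitecture("darknet14", 5)), 13)
  ## plus exactly one classification layer each
  for (nm in c("darknet9", "darknet14")) {
    roles <- vapply(buildArchitecture(nm, 5)@layers,
                    function(l) l$role, character(1))
    expect_equal(sum(roles == "classifier"), 1)
  }
})

test_that("the reduced MobileNet keeps 512 as its widest scale", {
  spec <- buildArchitecture("reduced_mobilenet", 7)
  expect_equal(maxFilterCount(spec), 512)
  filters <- vapply(spec@layers, function(l) l$filters, integer(1))
  expect_false(any(filters == 1024))
  ops <- vapply(spec@layers, function(l) l$op, character(1))
  ## one depthwise convolution per scale
  expect_equal(sum(ops == "depthwise_conv"), 4)
  pw <- which(ops == "pointwise_conv")
  expect_equal(vapply(spec@layers[pw], function(l) l$filters, integer(1)),
               c(64L, 128L, 256L, 512L))
  ## two fully connected layers in the head
  expect_equal(sum(ops == "fully_connected"), 2)
  ## batch normalisation follows every feature-extraction weighted layer
  weighted <- which(ops %in% c("conv", "depthwise_conv", "pointwise_conv"))
  expect_true(all(ops[weighted + 1] == "batch_norm"))
})

test_that("ResNet-18 reproduces the published residual layout", {
  spec <- buildArchitecture("resnet18", 5)
  expect_equal(countConvLayers(spec), 17)   # 1 stem + 8 blocks x 2
  ops <- vapply(spec@layers, function(l) l$op, character(1))
  expect_equal(sum(ops == "residual_block"), 8)
  expect_equal(sum(ops == "fully_connected"), 1)
  blocks <- spec@layers[ops == "residual_block"]
  expect_equal(vapply(blocks, function(l) l$filters, integer(1)),
               c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L))
})

test_that("parameter counts order darknet9 < darknet14 < resnet18", {
  p <- vapply(c("darknet9", "darknet14", "resnet18"),
              function(n) countParameters(buildArchitecture(n, 8)),
              integer(1))
  expect_lt(p["darknet9"], p["darknet14"])
  expect_lt(p["darknet14"], p["resnet18"])
})

test_that("unknown architectures and degenerate class counts are rejected", {
  expect_error(buildArchitecture("vgg16", 5))
  expect_error(buildArchitecture("darknet9", 1), "numClasses")
})

test_that("forward emits a probability simplex for every architecture", {
  imgs <- withr::with_seed(2, list(array(runif(64 * 64 * 3), c(64, 64, 3)),
                                   array(runif(64 * 64 * 3), c(64, 64, 3))))
  for (nm in c("darknet9", "darknet14", "reduced_mobilenet", "resnet18")) {
    arch <- buildArchitecture(nm, 4, c(64L, 64L))
    net <- withr::with_seed(1, wipid:::initNetwork(arch))
    cl <- new("WingClassifier", backend = "cnn", model = list(net = net),
              classes = letters[1:4], level = "subspecies")
    p <- forwardProbs(cl, imgs)
    expect_equal(dim(p), c(2, 4))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    ## duplicated inputs give identical rows
    p2 <- forwardProbs(cl, list(imgs[[1]], imgs[[1]]))
    expect_equal(p2[1, ], p2[2, ])
  }
})

test_that("training separates a two-class toy set and is deterministic", {
  tiny <- tinyDataset()
  labels <- manifestClasses(tiny$manifest)
  arch <- buildArchitecture("darknet9", 2, c(32L, 32L))
  cfg <- trainConfig(epochs = 12, batchSize = 8, seed = 5)
  m1 <- trainWingClassifier(tiny$images, labels, arch, cfg)
  expect_equal(mean(predictWing(m1, tiny$images) == labels), 1)
  ## final loss well below the initial loss
  expect_lt(utils::tail(lossTrace(m1), 1), lossTrace(m1)[1])
  ## same seed and data: identical loss traces
  m2 <- trainWingClassifier(tiny$images, labels, arch, cfg)
  expect_identical(lossTrace(m1), lossTrace(m2))
  ## single-class input is rejected
  expect_error(trainWingClassifier(tiny$images, rep("a", 20), arch, cfg),
               "2 classes")
})

test_that("zero learning rate freezes the loss trace", {
  tiny <- tinyDataset()
  labels <- manifestClasses(tiny$manifest)
  arch <- buildArchitecture("darknet9", 2, c(32L, 32L))
  ## one batch per epoch so every epoch sees the same set
  cfg <- trainConfig(epochs = 4, batchSize = 20, learningRate = 0, seed = 2)
  m <- trainWingClassifier(tiny$images, labels, arch, cfg)
  tr <- lossTrace(m)
  expect_true(all(abs(tr - tr[1]) < 1e-9))
})

test_that("training with augmentation runs and stays deterministic", {
  tiny <- tinyDataset()
  labels <- manifestClasses(tiny$manifest)
  arch <- buildArchitecture("darknet9", 2, c(32L, 32L))
  cfg <- trainConfig(epochs = 2, batchSize = 10, seed = 8)
  aug <- list(flipH = TRUE, flipV = TRUE, maxRotation = 10,
              zoomRange = c(0.95, 1.05))
  m1 <- trainWingClassifier(tiny$images, labels, arch, cfg, augment = aug)
  m2 <- trainWingClassifier(tiny$images, labels, arch, cfg, augment = aug)
  expect_identical(lossTrace(m1), lossTrace(m2))
})
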
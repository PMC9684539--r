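test_that("the grid enumerates exactly the 15 documented conditions in order", {
  grid <- robustnessGrid()
  expect_length(grid, 15)
  expect_equal(names(grid),
               c("none", "gaussian_blur", "lens_blur", "video_distortion",
                 "spread", "hurl", "rgb_noise", "cie_noise",
                 "occlude_trailing_edge", "occlude_outer_vein_V",
                 "occlude_inner_vein_VI", "raw_unprocessed", "flip_h",
                 "flip_v", "raw_resized"))
  ## the alternative legend vocabulary maps onto the same operations
  expect_equal(transformSpec("scatter")@kind, "spread")
  expect_equal(transformSpec("throws")@kind, "hurl")
  expect_equal(transformSpec("scrambling_rvb")@kind, "rgb_noise")
  expect_equal(transformSpec("scrambling_cie")@kind, "cie_noise")
  expect_error(transformSpec("solarize"), "unknown")
})

test_that("identity-parameter transforms are exact identities", {
  img <- fixtureWing()
  expect_identical(applyTransform(img, transformSpec("none")), img)
  expect_identical(applyTransform(img, transformSpec("hurl", probability = 0)),
                   img)
  f2 <- applyTransform(applyTransform(img, transformSpec("flip_v")),
                       transformSpec("flip_v"))
  expect_identical(f2, img)
  f2h <- applyTransform(applyTransform(img, transformSpec("flip_h")),
                        transformSpec("flip_h"))
  expect_identical(f2h, img)
})

test_that("spread permutes pixels, preserving per-channel value multisets", {
  img <- fixtureWing()
  out <- applyTransform(img, transformSpec("spread", radius = 4, seed = 6))
  for (c in 1:3)
    expect_identical(sort(as.vector(out[, , c])),
                     sort(as.vector(img[, , c])))
  expect_false(identical(out, img))
})

test_that("gaussian blur preserves the mean and vanishes with sigma", {
  img <- fixtureWing()
  b <- applyTransform(img, transformSpec("gaussian_blur", sigma = 2))
  ## normalised kernel + reflective boundary: mean preserved
  expect_equal(mean(b), mean(img), tolerance = 1e-6)
  tinySigma <- applyTransform(img, transformSpec("gaussian_blur", sigma = 0.05))
  expect_lt(max(abs(tinySigma - img)), 1e-3)
})

test_that("stochastic transforms are pure functions of (image, params, seed)", {
  img <- fixtureWing()
  for (kind in c("spread", "hurl", "rgb_noise", "cie_noise")) {
    a <- applyTransform(img, transformSpec(kind, seed = 9))
    b <- applyTransform(img, transformSpec(kind, seed = 9))
    d <- applyTransform(img, transformSpec(kind, seed = 10))
    expect_identical(a, b)
    expect_false(identical(a, d))
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(dim(a), dim(img))
  }
  ## deterministic kinds keep shape and range too
  for (kind in c("gaussian_blur", "lens_blur", "video_distortion")) {
    a <- applyTransform(img, transformSpec(kind))
    expect_equal(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("occlusions crop at the named boundaries and are idempotent", {
  img <- fixtureWing()
  g <- wipid:::wingGeometry(dim(img)[1:2])
  bg <- wipid:::.WIP_BACKGROUND
  area <- function(im) sum(im[, , 1] != bg | im[, , 2] != bg | im[, , 3] != bg)
  for (mode in c("trailing_edge", "outer_at_vein_V", "inner_at_vein_VI")) {
    occ <- occludeWing(img, mode)
    expect_lt(area(occ), area(img))          # wing area strictly decreases
    expect_identical(occludeWing(occ, mode), occ)  # idempotent
  }
  ## outer crop at vein V: everything beyond the vein is background
  occ <- occludeWing(img, "outer_at_vein_V")
  outer <- g$mask & g$u > wipid:::.WING_VEIN_V_U
  for (c in 1:3) expect_true(all(occ[, , c][outer] == bg))
  ## occlusion spares the inner part
  inner <- g$mask & g$u <= wipid:::.WING_VEIN_V_U
  expect_identical(occ[, , 1][inner], img[, , 1][inner])
})

test_that("robustness evaluation scores the grid with traffic lights", {
  tiny <- tinyDataset()
  labels <- manifestClasses(tiny$manifest)
  model <- meanColorClassifier()$fit(tiny$images, labels, "subspecies")
  grid <- robustnessGrid()
  rep <- evaluateRobustness(model, tiny$manifest, grid,
                            templates = tiny$templates,
                            images = tiny$images)
  expect_equal(dim(rep@grid), c(2, 15))
  ## condition "none" reproduces the base per-species accuracy exactly
  base <- vapply(split(predictWing(model, tiny$images) == labels, labels),
                 mean, numeric(1))
  expect_equal(rep@grid[, "none"], base[rownames(rep@grid)])
  ## legend rule: green iff 1, red iff 0, yellow in between
  expect_true(all(rep@lights[rep@grid == 1] == "green", na.rm = TRUE))
  expect_true(all(rep@lights[rep@grid == 0] == "red", na.rm = TRUE))
  expect_true(all(rep@lights[rep@grid > 0 & rep@grid < 1] == "yellow",
                  na.rm = TRUE))
  ## export round trip
  f <- tempfile(fileext = ".csv"); h <- tempfile(fileext = ".html")
  writeRobustnessReport(rep, f, h)
  expect_equal(dim(utils::read.csv(f, row.names = 1)), c(2, 15))
  expect_true(any(grepl("table", readLines(h))))
})

test_that("a species absent from training is red across all conditions", {
  tiny <- tinyDataset()
  labels <- manifestClasses(tiny$manifest)
  ## train on one class plus a dummy split of it, so the other class is unseen
  seen <- labels == "synthetica01"
  fakeLabels <- ifelse(seq_along(labels) %% 2 == 0, "synthetica01", "other")
  model <- meanColorClassifier()$fit(tiny$images[seen],
                                     fakeLabels[seen], "subspecies")
  rep <- evaluateRobustness(model, tiny$manifest,
                            robustnessGrid(), templates = tiny$templates,
                            images = tiny$images)
  expect_true(all(rep@lights["synthetica02", ] == "red"))
})
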
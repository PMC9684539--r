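tpl0 <- wellSeparatedTemplates(2)[[1]]

test_that("thickness maps are deterministic and respect the mask", {
  a <- generateThicknessMap(tpl0, "female", c(58L, 128L), seed = 3)
  b <- generateThicknessMap(tpl0, "female", c(58L, 128L), seed = 3)
  expect_identical(a@grid, b@grid)
  expect_true(all(a@grid >= 0))
  expect_true(all(a@grid[!a@mask] == 0))
  expect_setequal(names(a@veins), c("V", "VI", "trailing_edge"))
  c2 <- generateThicknessMap(tpl0, "female", c(58L, 128L), seed = 4)
  expect_false(identical(a@grid, c2@grid))  # noise field differs by seed
})

test_that("sex offset is the only male/female difference without noise", {
  tpl <- speciesTemplate("t", species = "t", baseThickness = 300,
                         sexOffset = 50, noiseScale = 0)
  f <- generateThicknessMap(tpl, "female", c(40L, 80L), seed = 1)
  m <- generateThicknessMap(tpl, "male", c(40L, 80L), seed = 1)
  d <- (m@grid - f@grid)[f@mask]
  expect_true(all(abs(d - 50) < 1e-9))
  ## zero offset and zero noise: sexes identical, pure function of patches
  tpl2 <- speciesTemplate("t2", species = "t2", baseThickness = 300,
                          sexOffset = 0, noiseScale = 0)
  f2 <- generateThicknessMap(tpl2, "female", c(40L, 80L), seed = 1)
  m2 <- generateThicknessMap(tpl2, "male", c(40L, 80L), seed = 99)
  expect_identical(f2@grid, m2@grid)
})

test_that("templates violating physical thickness bounds are rejected", {
  expect_error(speciesTemplate("bad", species = "b", baseThickness = 40,
                               noiseScale = 0), "physical band")
  expect_error(speciesTemplate("bad", species = "b", baseThickness = 1490,
                               sexOffset = 50, noiseScale = 0), "physical band")
  expect_error(
    speciesTemplate("bad", species = "b",
                    patches = data.frame(u = 1.4, v = 0.5, radius = 0.1,
                                         delta = 50)), "unit wing region")
})

test_that("rendering: background outside the mask, uniform for a flat film", {
  g <- wipid:::wingGeometry(c(40L, 80L))
  zero <- new("ThicknessMap", grid = matrix(0, 40, 80), mask = g$mask,
              veins = g$veins)
  img <- renderWing(zero)@image
  inMask <- img[cbind(rep(which(g$mask), 3),
                      rep(1:3, each = sum(g$mask)))]
  ## vanishing film: every in-mask pixel sits at the background level
  expect_true(all(abs(inMask - wipid:::.WIP_BACKGROUND) < 1e-9))
  outPix <- img[cbind(rep(which(!g$mask), 3),
                      rep(1:3, each = sum(!g$mask)))]
  expect_true(all(outPix == wipid:::.WIP_BACKGROUND))
  ## thickness outside the mask is structurally impossible
  badGrid <- matrix(0, 40, 80); badGrid[!g$mask] <- 100
  expect_error(new("ThicknessMap", grid = badGrid, mask = g$mask,
                   veins = g$veins), "outside the mask")
})

test_that("a thickness ramp renders the four reported hue families", {
  g <- wipid:::wingGeometry(c(60L, 120L))
  ramp <- matrix(rep(seq(100, 900, length.out = 120), each = 60), 60, 120)
  ramp[!g$mask] <- 0
  tm <- new("ThicknessMap", grid = ramp, mask = g$mask, veins = g$veins)
  img <- renderWing(tm)@image
  px <- cbind(img[, , 1][g$mask], img[, , 2][g$mask], img[, , 3][g$mask])
  hsv <- t(apply(px, 1, function(v)
    grDevices::rgb2hsv(v[1], v[2], v[3], maxColorValue = 1)))
  vivid <- hsv[, 2] > 0.3 & hsv[, 3] > 0.15
  bins <- floor(hsv[vivid, 1] * 12) %% 12     # 12-bin hue histogram
  present <- unique(bins)
  expect_true(any(present %in% c(0, 11)))    # red family
  expect_true(any(present %in% c(1, 2)))     # yellow
  expect_true(any(present %in% c(3, 4)))     # green
  expect_true(any(present %in% c(6, 7, 8)))  # blue
})

test_that("dataset generation is reproducible byte-for-byte and honours counts", {
  tpl <- wellSeparatedTemplates(2)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generateDataset(tpl, c(synth01 = 3L, synth02 = 2L), seed = 9,
                        outputDir = d1, imageSize = c(32L, 32L))
  m2 <- generateDataset(tpl, c(synth01 = 3L, synth02 = 2L), seed = 9,
                        outputDir = d2, imageSize = c(32L, 32L))
  expect_equal(nrow(manifestRecords(m1)), 5)
  expect_equal(as.vector(table(manifestClasses(m1))[c("synthetica01",
                                                      "synthetica02")]),
               c(3L, 2L))
  f1 <- list.files(d1, "png$", full.names = TRUE)
  f2 <- list.files(d2, "png$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  ## all-zero counts: empty manifest, no images
  d0 <- file.path(tempdir(), "ds0")
  m0 <- generateDataset(tpl, c(synth01 = 0L, synth02 = 0L), seed = 9,
                        outputDir = d0)
  expect_equal(nrow(manifestRecords(m0)), 0)
  expect_length(list.files(d0, "png$"), 0)
})

test_that("the shipped template fixture matches the reference database table", {
  tpl <- glossinaTemplates()
  expect_length(tpl, 23)
  counts <- attr(tpl, "counts")
  species <- vapply(tpl, function(t) t@species, character(1))
  expect_equal(length(unique(vapply(tpl, function(t)
    coarsenLabel(data.frame(genus = t@genus, complex = t@complex,
                            species = t@species, subspecies = t@subspecies),
                 "subspecies"), character(1)))), 23)
  ## the imbalanced per-class counts of the reference database
  expect_equal(unname(counts[c("palpalis_palpalis", "palpalis_gambiensis",
                               "fuscipes_fuscipes", "morsitans_morsitans",
                               "pallidipes", "haningtoni")]),
               c(620L, 195L, 301L, 146L, 117L, 1L))
  expect_equal(sum(counts), 1762L)
  expect_equal(range(counts), c(1L, 620L))
  ## complex membership is total over the fixture taxa
  cpx <- vapply(tpl, function(t) t@complex, character(1))
  expect_setequal(stats::na.omit(unique(cpx)),
                  c("fuscipes", "palpalis", "morsitans"))
  ## round trip through the plain-text serialisation
  f <- tempfile(fileext = ".tsv")
  writeTemplateSet(tpl, counts, f)
  back <- readTemplateSet(f)
  expect_equal(attr(back, "counts"), counts)
  expect_equal(back[[5]]@patches, tpl[[5]]@patches)
})
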
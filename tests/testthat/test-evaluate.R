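test_that("label coarsening follows the complex membership rules", {
  df <- data.frame(
    genus = "Glossina",
    complex = c("palpalis", NA, NA, "morsitans"),
    species = c("palpalis", "pallidipes", "fuscipes", "morsitans"),
    subspecies = c("gambiensis", NA, "quazensis", "submorsitans"),
    stringsAsFactors = FALSE)
  expect_equal(coarsenLabel(df, "complex"),
               c("palpalis", "unassigned", "fuscipes", "morsitans"))
  expect_equal(coarsenLabel(df, "genus"), rep("Glossina", 4))
  expect_equal(coarsenLabel(df, "subspecies"),
               c("palpalis_gambiensis", "pallidipes", "fuscipes_quazensis",
                 "morsitans_submorsitans"))
})

test_that("cross-validation scores every record exactly once, reproducibly", {
  tiny <- tinyDataset()
  folds <- makeFolds(tiny$manifest, k = 2, seed = 3)
  cls <- meanColorClassifier()
  p1 <- runCV(tiny$manifest, folds, cls, images = tiny$images)
  p2 <- runCV(tiny$manifest, folds, cls, images = tiny$images)
  expect_identical(cvPredictions(p1), cvPredictions(p2))
  df <- cvPredictions(p1)
  expect_setequal(df$id, manifestRecords(tiny$manifest)$id)
  expect_equal(anyDuplicated(df$id), 0)
  ## mean accuracy is the fold-size-weighted average of fold accuracies
  perFold <- vapply(split(df, df$fold),
                    function(d) mean(d$true == d$pred), numeric(1))
  sizes <- vapply(split(df, df$fold), nrow, integer(1))
  expect_equal(mean(df$true == df$pred),
               sum(perFold * sizes) / sum(sizes))
  ## well-separated templates: the mean-colour model recovers them
  expect_gt(mean(df$true == df$pred), 0.9)
})

test_that("confusion matrices count correctly at every level", {
  df <- data.frame(
    id = sprintf("r%02d", 1:8), genus = "Glossina",
    complex = c(rep("palpalis", 4), rep(NA, 4)),
    species = c(rep("palpalis", 4), rep("pallidipes", 4)),
    subspecies = c(rep("palpalis", 2), rep("gambiensis", 2), rep(NA, 4)),
    stringsAsFactors = FALSE)
  df$true <- coarsenLabel(df, "subspecies")
  df$pred <- c("palpalis_palpalis", "palpalis_gambiensis",
               "palpalis_gambiensis", "palpalis_gambiensis",
               "pallidipes", "pallidipes", "pallidipes", "palpalis_palpalis")
  df$fold <- 0L; df$max_prob <- 1
  ps <- new("PredictionSet", predictions = df, level = "subspecies")
  cm <- confusionWip(ps, "subspecies")
  expect_equal(sum(cm@counts), 8)
  expect_equal(accuracy(cm), 6 / 8)
  ## row sums equal per-class test counts
  expect_equal(unname(rowSums(cm@counts)),
               unname(as.vector(table(factor(df$true, cm@classes)))))
  ## genus level collapses everything correct
  expect_equal(accuracy(confusionWip(ps, "genus")), 1)
  ## complex level: palpalis vs unassigned
  cmc <- confusionWip(ps, "complex")
  expect_setequal(cmc@classes, c("palpalis", "unassigned"))
  expect_equal(accuracy(cmc), 7 / 8)
})

test_that("a perfect predictor yields a diagonal confusion matrix", {
  df <- labelFrame(c(3, 4))
  df$true <- coarsenLabel(df, "subspecies")
  df$pred <- df$true
  df$fold <- 0L; df$max_prob <- 1
  ps <- new("PredictionSet", predictions = df, level = "subspecies")
  cm <- confusionWip(ps)
  expect_true(all(cm@counts[upper.tri(cm@counts) | lower.tri(cm@counts)] == 0))
  expect_equal(accuracy(cm), 1)
  ## a constant predictor on a balanced two-class set scores 1/2
  df$pred <- df$true[1]
  ps2 <- new("PredictionSet",
             predictions = transform(df, pred = rep(coarsenLabel(df, "subspecies")[1],
                                                    nrow(df))),
             level = "subspecies")
  dfb <- labelFrame(c(5, 5)); dfb$true <- coarsenLabel(dfb, "subspecies")
  dfb$pred <- dfb$true[1]; dfb$fold <- 0L; dfb$max_prob <- 1
  expect_equal(accuracy(confusionWip(
    new("PredictionSet", predictions = dfb, level = "subspecies"))), 0.5)
})

test_that("accuracy is monotone under taxonomic coarsening", {
  species <- c("palpalis", "palpalis", "fuscipes", "morsitans", "pallidipes",
               "austeni")
  subspecies <- c("palpalis", "gambiensis", "fuscipes", "morsitans", NA, NA)
  complexes <- c("palpalis", "palpalis", "fuscipes", "morsitans", NA, NA)
  for (s in 1:10) {
    n <- 40
    pick <- withr::with_seed(s, sample(length(species), n, replace = TRUE))
    pred <- withr::with_seed(s + 100, sample(length(species), n, replace = TRUE))
    df <- data.frame(
      id = sprintf("r%03d", 1:n), genus = "Glossina",
      complex = complexes[pick], species = species[pick],
      subspecies = subspecies[pick], stringsAsFactors = FALSE)
    df$true <- coarsenLabel(df, "subspecies")
    df$pred <- coarsenLabel(data.frame(genus = "Glossina",
                                       complex = complexes[pred],
                                       species = species[pred],
                                       subspecies = subspecies[pred]),
                            "subspecies")
    df$fold <- 0L; df$max_prob <- 1
    ps <- new("PredictionSet", predictions = df, level = "subspecies")
    accG <- accuracyAtLevel(ps, "genus")
    accC <- accuracyAtLevel(ps, "complex", membersOnly = TRUE)
    accF <- accuracyAtLevel(ps, "subspecies")
    expect_gte(accG, accC)
    expect_gte(accC,
               mean(df$true[coarsenLabel(df, "complex") != "unassigned"] ==
                    df$pred[coarsenLabel(df, "complex") != "unassigned"]))
    expect_gte(accG, accF)
  }
})

test_that("negative samples flow through genus-level evaluation", {
  tpl <- c(wellSeparatedTemplates(2), list(negativeTemplate()))
  cnt <- c(synth01 = 6L, synth02 = 6L, negative01 = 6L)
  dir <- file.path(tempdir(), "wipid-neg")
  mf <- generateDataset(tpl, cnt, seed = 31, outputDir = dir,
                        imageSize = c(32L, 32L))
  expect_setequal(unique(coarsenLabel(manifestRecords(mf), "genus")),
                  c("Glossina", "Insecta"))
  folds <- makeFolds(mf, k = 2, seed = 31)
  ps <- runCV(mf, folds, meanColorClassifier())
  ## genus-level readout separates Glossina from the negative class
  expect_gte(accuracyAtLevel(ps, "genus"), 0.8)
})

test_that("prediction sets and confusion matrices export as CSV", {
  tiny <- tinyDataset()
  folds <- makeFolds(tiny$manifest, k = 2, seed = 3)
  ps <- runCV(tiny$manifest, folds, meanColorClassifier(),
              images = tiny$images)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePredictions(ps, f1)
  writeConfusion(confusionWip(ps), f2)
  expect_equal(nrow(utils::read.csv(f1)), 20)
  expect_equal(names(utils::read.csv(f1)),
               c("id", "true", "pred", "fold", "max_prob"))
  rep <- accuracyReport(ps)
  expect_true(any(grepl("accuracy genus", rep)))
})
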
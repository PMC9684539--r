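# Shared synthetic fixtures, generated once per test session.
.fixtureEnv <- new.env(parent = emptyenv())

# Small two-template dataset at reduced resolution (fast unit tests).
tinyDataset <- function() {
  if (!is.null(.fixtureEnv$tiny)) return(.fixtureEnv$tiny)
  tpl <- wellSeparatedTemplates(2)
  dir <- file.path(tempdir(), "wipid-tiny")
  mf <- generateDataset(tpl, counts = c(synth01 = 10L, synth02 = 10L),
                        seed = 42, outputDir = dir,
                        imageSize = c(32L, 32L))
  .fixtureEnv$tiny <- list(templates = tpl, manifest = mf,
                           images = loadImages(mf))
  .fixtureEnv$tiny
}

# One full-resolution rendered wing (for descriptor / transform tests).
fixtureWing <- function() {
  if (!is.null(.fixtureEnv$wing)) return(.fixtureEnv$wing)
  tpl <- wellSeparatedTemplates(3)[[3]]
  tm <- generateThicknessMap(tpl, "female", c(116L, 256L), seed = 7)
  .fixtureEnv$wing <- renderWing(tm, templateId = tpl@template_id)@image
  .fixtureEnv$wing
}

# A manifest data.frame row set with arbitrary class sizes (no images).
labelFrame <- function(sizes, species = NULL) {
  if (is.null(species)) species <- sprintf("sp%02d", seq_along(sizes))
  do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(id = sprintf("%s_%03d", species[i], seq_len(sizes[i])),
               path = "unused", genus = "Glossina", complex = NA_character_,
               species = species[i], subspecies = NA_character_,
               sex = "female", source = "test", seed = 0L,
               stringsAsFactors = FALSE)))
}

# A nearest-mean-colour classifier factory: fast stand-in backend for
# exercising the cross-validation plumbing without network training.
meanColorClassifier <- function() {
  list(name = "meancolor",
       fit = function(images, labels, level) {
         feats <- t(vapply(images, function(im) apply(im, 3, mean),
                           numeric(3)))
         classes <- sort(unique(labels))
         centers <- t(vapply(classes, function(cl)
           colMeans(feats[labels == cl, , drop = FALSE]), numeric(3)))
         fn <- function(imgs) {
           f <- t(vapply(imgs, function(im) apply(im, 3, mean), numeric(3)))
           d2 <- outer(rowSums(f^2), rep(1, nrow(centers))) -
                 2 * f %*% t(centers) +
                 outer(rep(1, nrow(f)), rowSums(centers^2))
           s <- exp(-d2)
           s / rowSums(s)
         }
         new("WingClassifier", backend = "custom",
             model = list(fn = fn), classes = classes, level = level)
       })
}
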
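test_that("the exact count law holds for all rounds and original flags", {
  img <- noiseImage(size = 20L, seed = 1)
  for (rounds in 1:3) {
    for (keep in c(TRUE, FALSE)) {
      cfg <- CascadeConfig(rounds = rounds, includeOriginal = keep)
      expect_identical(expansionFactor(cfg), 5L * rounds + as.integer(keep))
      expect_length(cascadeOne(img, cfg), 5L * rounds + as.integer(keep))
    }
  }
  # defaults: three rounds plus the original = 16 outputs per source
  expect_length(cascadeOne(img, CascadeConfig()), 16L)
  expect_length(cascadeOne(img, CascadeConfig(rounds = 1, includeOriginal = FALSE)), 5L)
})

test_that("every cascade output keeps the source label and dimensions", {
  img <- noiseImage(label = "SO", size = 24L, seed = 2)
  out <- cascadeOne(img, CascadeConfig())
  for (rec in out) {
    expect_identical(imageLabel(rec), "SO")
    expect_identical(dim(rec), dim(img))
  }
})

test_that("transform chains follow one of the five branch paths or the original", {
  img <- noiseImage(size = 20L, seed = 3)
  out <- cascadeOne(img, CascadeConfig(rounds = 2))
  paths <- vapply(out, function(rec)
    paste(vapply(transformChain(rec), function(e) e$name, ""), collapse = ">"),
    "")
  allowed <- c("rotate", "rotate>hist_equalize", "rotate>gaussian_noise",
               "rotate>hist_equalize>scale_in", "rotate>gaussian_noise>scale_in",
               "")
  expect_true(all(paths %in% allowed))
  expect_identical(sum(paths == ""), 1L)  # exactly the retained original
  # each of the five branch paths appears once per round
  expect_true(all(table(paths[paths != ""]) == 2L))
})

test_that("cascade results are seed-reproducible and order-independent", {
  img <- noiseImage(size = 20L, seed = 4, sourceId = "fixed_id")
  a <- cascadeOne(img, CascadeConfig(masterSeed = 42))
  b <- cascadeOne(img, CascadeConfig(masterSeed = 42))
  for (i in seq_along(a)) expect_identical(pixelData(a[[i]]), pixelData(b[[i]]))
  c2 <- cascadeOne(img, CascadeConfig(masterSeed = 43))
  expect_false(identical(pixelData(a[[1]]), pixelData(c2[[1]])))
})

test_that("no cascade output aliases the input raster", {
  img <- noiseImage(size = 20L, seed = 5)
  out <- cascadeOne(img, CascadeConfig(rounds = 1, includeOriginal = FALSE))
  for (rec in out) expect_false(identical(pixelData(rec), pixelData(img)))
})

test_that("augmentClass multiplies counts exactly and rejects mixed labels", {
  imgs <- lapply(1:3, function(s) noiseImage(label = "EF", size = 20L, seed = s,
                                             sourceId = paste0("e", s)))
  expect_length(augmentClass(imgs, CascadeConfig()), 48L)
  expect_length(augmentClass(list(), CascadeConfig()), 0L)
  mixed <- c(imgs, list(noiseImage(label = "TR", size = 20L, seed = 9)))
  expect_error(augmentClass(mixed), "single class")
})

test_that("augmentDataset expands per-class counts by the expansion factor", {
  d <- PestImageSet(c(
    lapply(1:3, function(s) noiseImage(label = "AJ", size = 16L, seed = s,
                                       sourceId = paste0("a", s))),
    lapply(1:2, function(s) noiseImage(label = "LR", size = 16L, seed = 10 + s,
                                       sourceId = paste0("l", s)))),
    classes = c("AJ", "LR"))
  cfg <- CascadeConfig(masterSeed = 7)
  out <- augmentDataset(d, cfg)
  expect_identical(classNames(out), classNames(d))
  expect_identical(classCounts(out), c(AJ = 48L, LR = 32L))
  out2 <- augmentDataset(d, cfg)
  expect_identical(lapply(out@images, pixelData), lapply(out2@images, pixelData))
})
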
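smallSet <- function(n = 3L, size = 24L) {
  PestImageSet(c(
    lapply(seq_len(n), function(s) noiseImage(label = "AJ", size = size,
      seed = s, sourceId = paste0("a", s))),
    lapply(seq_len(n), function(s) noiseImage(label = "SO", size = size,
      seed = 10 + s, sourceId = paste0("s", s)))),
    classes = c("AJ", "SO"))
}

test_that("all eleven presets are registered exactly once", {
  tab <- strategyPresets()
  expect_identical(tab$id, 0:10)
  expect_false(anyDuplicated(tab$id) > 0)
  expect_identical(tab$name[1], "No augmentation")
  expect_identical(tab$name[11], "Proposed approach")
})

test_that("baseline set 0 returns the dataset record for record", {
  d <- smallSet()
  out <- buildStrategy(d, 0, seed = 1)
  expect_identical(nImages(out), nImages(d))
  for (i in seq_len(nImages(d)))
    expect_identical(pixelData(out[[i]]), pixelData(d[[i]]))
})

test_that("strategy ids outside 0..10 are rejected", {
  expect_error(buildStrategy(smallSet(), 11), "0..10")
  expect_error(buildStrategy(smallSet(), -1), "0..10")
})

test_that("fan-out sizes are fixed and originals are retained", {
  d <- smallSet()
  n <- nImages(d)
  # stochastic atomic strategies: originals + 2 per source
  for (id in c(1, 4, 5, 6, 8, 9)) {
    expect_identical(nImages(buildStrategy(d, id, seed = 3)), n + 2L * n,
                     label = paste("strategy", id))
  }
  # flips and scale in/out: originals + exactly the two variants
  for (id in c(2, 7)) {
    expect_identical(nImages(buildStrategy(d, id, seed = 3)), n + 2L * n)
  }
  # contrast enhancement is deterministic: one distinct copy per source
  expect_identical(nImages(buildStrategy(d, 3, seed = 3)), n + n)
  # originals can be dropped
  expect_identical(nImages(buildStrategy(d, 1, seed = 3,
                                         includeOriginal = FALSE)), 2L * n)
})

test_that("every augmented record of every strategy keeps its source label", {
  d <- smallSet()
  for (id in 1:10) {
    out <- buildStrategy(d, id, seed = 2)
    src <- vapply(d@images, sourceId, "")
    lab <- stats::setNames(vapply(d@images, imageLabel, ""), src)
    for (rec in out@images) {
      expect_identical(imageLabel(rec), unname(lab[sourceId(rec)]),
                       label = paste("strategy", id))
    }
  }
})

test_that("mixup strategy records are convex combinations of same-class inputs", {
  d <- smallSet()
  out <- buildStrategy(d, 6, seed = 4, includeOriginal = FALSE)
  byId <- stats::setNames(d@images, vapply(d@images, sourceId, ""))
  for (rec in out@images) {
    chain <- transformChain(rec)
    expect_identical(chain[[1]]$name, "mixup")
    expect_equal(chain[[1]]$params$lambda, 0.2)
    first <- byId[[sourceId(rec)]]
    partner <- byId[[chain[[1]]$params$partner]]
    expect_identical(imageLabel(partner), imageLabel(first))
    lo <- pmin(pixelData(first), pixelData(partner))
    hi <- pmax(pixelData(first), pixelData(partner))
    expect_true(all(pixelData(rec) >= lo - 1L) &&
                all(pixelData(rec) <= hi + 1L))
  }
})

test_that("the proposed strategy follows the cascade count law", {
  d <- smallSet(n = 2L)
  out <- buildStrategy(d, 10, seed = 5)
  expect_identical(nImages(out), 4L * 16L)
  expect_identical(classCounts(out), c(AJ = 32L, SO = 32L))
})

test_that("strategy builds are reproducible for a fixed seed", {
  d <- smallSet()
  for (id in c(1, 5, 6, 10)) {
    a <- buildStrategy(d, id, seed = 11)
    b <- buildStrategy(d, id, seed = 11)
    expect_identical(lapply(a@images, pixelData), lapply(b@images, pixelData),
                     label = paste("strategy", id))
  }
})

test_that("runComparison yields one seed-reproducible row per strategy", {
  d <- syntheticPestSet(counts = c(AJ = 6, SO = 6, EF = 6), size = 48,
                        seed = 3)
  cfg <- TrainConfig(epochs = 3, seed = 1)
  res <- runComparison(d, c(0, 2), config = cfg, seed = 9)
  expect_identical(nrow(res), 2L)
  expect_identical(res$id, c(0L, 2L))
  expect_true(all(res$valAccuracy >= 0 & res$valAccuracy <= 1))
  res2 <- runComparison(d, c(0, 2), config = cfg, seed = 9)
  expect_identical(res$valAccuracy, res2$valAccuracy)
  expect_error(runComparison(d, integer(0)), "non-empty")
})
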
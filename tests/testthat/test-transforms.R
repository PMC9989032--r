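test_that("rotation identities: theta = 0 and 360 leave pixels untouched", {
  img <- gradientImage(size = 7L)
  expect_identical(pixelData(rotateImage(img, 0)), pixelData(img))
  expect_identical(pixelData(rotateImage(img, 360)), pixelData(img))
})

test_that("90-degree rotation is the hand-derived pixel permutation", {
  # 2x2 raster [[a, b], [c, d]] per channel rotates to [[b, d], [a, c]]
  m <- array(0L, c(2, 2, 3))
  for (ch in 1:3) m[, , ch] <- matrix(c(1L, 3L, 2L, 4L) + 10L * ch, 2, 2)
  img <- PestImage(m, "AJ")
  out <- pixelData(rotateImage(img, 90, interpolation = "nearest"))
  for (ch in 1:3) {
    expect_identical(out[, , ch],
                     matrix(c(2L, 1L, 4L, 3L) + 10L * ch, 2, 2))
  }
})

test_that("rotation by theta then -theta at right angles recovers the original", {
  img <- noiseImage(size = 9L, seed = 2)
  for (theta in c(90, 180, 270)) {
    back <- rotateImage(rotateImage(img, theta), -theta)
    expect_identical(pixelData(back), pixelData(img))
  }
})

test_that("general-angle rotation keeps dimensions and the intensity range", {
  img <- noiseImage(size = 21L, seed = 3)
  for (theta in c(37, 150, 222.5)) {
    for (interp in c("bilinear", "nearest")) {
      out <- rotateImage(img, theta, interpolation = interp)
      expect_identical(dim(out), dim(img))
      expect_true(min(pixelData(out)) >= 0L && max(pixelData(out)) <= 255L)
    }
  }
  # constant fill marks out-of-canvas corners with the fill value
  filled <- rotateImage(constantImage(200, size = 11L), 45, fill = 0)
  expect_identical(pixelData(filled)[1, 1, 1], 0L)
})

test_that("flips are involutions and reverse the expected axis", {
  img <- noiseImage(size = 10L, seed = 5)
  expect_identical(pixelData(flipImage(flipImage(img, "horizontal"), "horizontal")),
                   pixelData(img))
  expect_identical(pixelData(flipImage(flipImage(img, "vertical"), "vertical")),
                   pixelData(img))
  row <- PestImage(array(c(10L, 20L, 30L), c(1, 3, 3)), "AJ")
  expect_identical(pixelData(flipImage(row, "horizontal"))[1, , 1],
                   c(30L, 20L, 10L))
  col <- PestImage(array(c(10L, 20L, 30L), c(3, 1, 3)), "AJ")
  expect_identical(pixelData(flipImage(col, "vertical"))[, 1, 1],
                   c(30L, 20L, 10L))
})

test_that("zero-sigma noise is the identity and moments are recovered", {
  img <- constantImage(128, size = 100L)  # 3e4 pixels
  expect_identical(pixelData(addGaussianNoise(img, sigma = 0)),
                   pixelData(img))
  out <- pixelData(addGaussianNoise(img, sigma = 10, seed = 11L))
  expect_lt(abs(mean(out) - 128), 0.5)
  expect_lt(abs(stats::sd(out) - 10), 1)
  # clipping holds even for destructive sigma
  wild <- pixelData(addGaussianNoise(img, sigma = 500, seed = 12L))
  expect_true(min(wild) >= 0L && max(wild) <= 255L)
})

test_that("histogram equalization matches the four-pixel hand oracle", {
  m <- array(0L, c(2, 2, 3))
  for (ch in 1:3) m[, , ch] <- matrix(c(52L, 61L, 55L, 59L), 2, 2)
  out <- pixelData(equalizeHist(PestImage(m, "AJ")))
  # cdf_min = 1, N = 4: 52 -> 0, 55 -> 85, 59 -> 170, 61 -> 255
  for (ch in 1:3) {
    expect_identical(out[, , ch], matrix(c(0L, 255L, 85L, 170L), 2, 2))
  }
})

test_that("equalization conventions: constant unchanged, uniform near-identity, monotone", {
  expect_identical(pixelData(equalizeHist(constantImage(77))),
                   pixelData(constantImage(77)))
  # a channel uniform over all 256 levels maps (almost) to itself
  px <- array(rep(0:255, 3), c(16, 16, 3))
  out <- pixelData(equalizeHist(PestImage(px, "AJ")))
  expect_lte(max(abs(out - px)), 1L)
  # per-channel monotone non-decreasing on arbitrary content
  img <- noiseImage(size = 24L, seed = 8)
  eq <- pixelData(equalizeHist(img))
  for (ch in 1:3) {
    o <- order(pixelData(img)[, , ch])
    expect_true(all(diff(eq[, , ch][o]) >= 0L))
  }
})

test_that("equalization is idempotent up to one intensity level", {
  for (seed in c(3, 14)) {
    e1 <- equalizeHist(noiseImage(size = 32L, seed = seed))
    e2 <- equalizeHist(e1)
    expect_lte(max(abs(pixelData(e2) - pixelData(e1))), 1L)
  }
  e1 <- equalizeHist(generatePestImage("SO", size = 64, seed = 5))
  e2 <- equalizeHist(e1)
  expect_lte(max(abs(pixelData(e2) - pixelData(e1))), 1L)
})

test_that("scale-in crops centrally and resizes back", {
  img <- noiseImage(size = 12L, seed = 6)
  expect_identical(pixelData(scaleIn(img, 1)), pixelData(img))
  # zoom = 2 on 4x4: output derives only from the central 2x2 block
  m <- array(0L, c(4, 4, 3))
  m[2:3, 2:3, ] <- 100L
  m[c(1, 4), c(1, 4), ] <- 255L  # corners must not leak in
  out <- pixelData(scaleIn(PestImage(m, "AJ"), 2))
  expect_true(all(out == 100L))
  expect_identical(dim(scaleIn(img, 1.7)), dim(img))
  expect_error(scaleIn(img, 13), "below one pixel")
  out2 <- scaleOut(img, 1.25)
  expect_identical(dim(out2), dim(img))
  expect_identical(pixelData(scaleOut(img, 1)), pixelData(img))
})

test_that("mixup endpoints, hand value, and convexity bounds hold", {
  a <- constantImage(100, sourceId = "a")
  b <- constantImage(200, sourceId = "b")
  expect_identical(pixelData(mixupImages(a, b, 1)), pixelData(a))
  expect_identical(pixelData(mixupImages(a, b, 0)), pixelData(b))
  expect_true(all(pixelData(mixupImages(a, b, 0.2)) == 180L))
  # convexity: output bounded by per-pixel min and max of the inputs
  x <- noiseImage(size = 16L, seed = 21, sourceId = "x")
  y <- noiseImage(size = 16L, seed = 22, sourceId = "y")
  mixed <- pixelData(mixupImages(x, y, 0.4))
  lo <- pmin(pixelData(x), pixelData(y))
  hi <- pmax(pixelData(x), pixelData(y))
  expect_true(all(mixed >= lo - 1L) && all(mixed <= hi + 1L))
  # partner with different dimensions is resized to the first image
  z <- noiseImage(size = 8L, seed = 23, sourceId = "z")
  expect_identical(dim(mixupImages(x, z, 0.5)), dim(x))
})

test_that("mixup rejects cross-class pairs and self-pairing", {
  a <- constantImage(10, label = "AJ", sourceId = "a")
  b <- constantImage(20, label = "SO", sourceId = "b")
  expect_error(mixupImages(a, b, 0.2), "same class")
  expect_error(mixupImages(a, a, 0.2), "itself")
})
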
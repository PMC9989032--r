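test_that("PestImage enforces the 8-bit three-channel contract", {
  expect_error(PestImage(array(0L, c(4, 4, 4)), "AJ"), "3 channels")
  expect_error(new("PestImage", pixels = array(300L, c(2, 2, 3)),
                   label = "AJ", sourceId = "x", transformChain = list()),
               "\\[0, 255\\]")
  expect_error(PestImage(array(0L, c(2, 2, 3)), label = ""), "label")
  # numeric input is quantized with round-half-away-from-zero and clipped
  img <- PestImage(array(c(0.4, 0.5, 254.5, 300, -5, 1.49), c(1, 2, 3)), "AJ")
  expect_identical(as.vector(pixelData(img)), c(0L, 1L, 255L, 255L, 0L, 1L))
})

test_that("an untransformed record has an empty chain and chains append", {
  img <- gradientImage()
  expect_length(transformChain(img), 0)
  r <- rotateImage(img, 45)
  expect_length(transformChain(r), 1)
  expect_identical(transformChain(r)[[1]]$name, "rotate")
  r2 <- equalizeHist(r)
  expect_length(transformChain(r2), 2)
  # input chain is the prefix of the output chain
  expect_identical(transformChain(r2)[[1]], transformChain(r)[[1]])
})

test_that("every registered transform preserves label, shape and range", {
  partner <- noiseImage(label = "AJ", seed = 99, sourceId = "partner")
  for (seed in 1:3) {
    img <- noiseImage(label = "AJ", size = 20L, seed = seed)
    for (nm in registeredTransforms()) {
      out <- applyTransform(img, specForTransform(nm, partner = partner))
      expect_identical(imageLabel(out), imageLabel(img), label = nm)
      expect_identical(dim(out), dim(img), label = nm)
      px <- pixelData(out)
      expect_true(is.integer(px) && min(px) >= 0L && max(px) <= 255L,
                  label = nm)
      expect_length(transformChain(out), 1)
    }
  }
})

test_that("the same image, spec and seed give bit-identical output", {
  img <- noiseImage(size = 24L, seed = 4)
  for (nm in c("gaussian_noise", "pca_augment")) {
    spec <- specForTransform(nm)
    expect_identical(pixelData(applyTransform(img, spec)),
                     pixelData(applyTransform(img, spec)), label = nm)
  }
})

test_that("unknown transform names and bad parameters are rejected", {
  expect_error(TransformSpec("swirl"), "unknown transform")
  img <- gradientImage()
  expect_error(rotateImage(img, Inf), "finite")
  expect_error(addGaussianNoise(img, sigma = -1), "sigma")
  expect_error(scaleIn(img, 0.5), "zoom")
})

test_that("PestImageSet enforces class membership and counts are consistent", {
  a <- gradientImage("AJ", sourceId = "a")
  b <- gradientImage("SO", sourceId = "b")
  expect_error(PestImageSet(list(a, b), classes = "AJ"), "not in the class set")
  d <- PestImageSet(list(a, b, gradientImage("AJ", sourceId = "c")),
                    classes = c("AJ", "SO", "EF"))
  expect_identical(sum(classCounts(d)), nImages(d))
  expect_identical(classCounts(d), c(AJ = 2L, SO = 1L, EF = 0L))
  expect_identical(classNames(d), c("AJ", "SO", "EF"))
  expect_identical(imageLabels(d), c("AJ", "SO", "AJ"))
  sub <- classSubset(d, "AJ")
  expect_identical(nImages(sub), 2L)
  expect_identical(sourceIds(d[1:2]), c("a", "b"))
  expect_identical(sourceId(d[[2]]), "b")
})
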
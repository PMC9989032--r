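# The cascaded manipulation-based augmentation pipeline.
#
# One pass over a source image: draw three independent random rotations;
# store the first rotated copy; histogram-equalize the second and store it;
# add Gaussian noise to the third and store it; then central-crop scale the
# enhanced and the noisy copies and store both. Five stored images per pass.
# With `rounds` passes plus the retained original, each source image expands
# into 5 * rounds + 1 derived images (16 with the defaults).

#' Expansion factor of a cascade configuration
#'
#' The exact number of output images per source image:
#' `5 * rounds + includeOriginal`. The defaults give 16, so a 54-image class
#' expands to 864 images and a 44-image class to 704.
#'
#' @param config a [CascadeConfig-class].
#' @return integer expansion factor.
#' @rdname expansionFactor
#' @export
setMethod("expansionFactor", "CascadeConfig", function(config) {
  5L * config@rounds + as.integer(config@includeOriginal)
})

#' Run the augmentation cascade on one image
#'
#' Applies the cascade to a single source image. Randomness (the three
#' rotation angles and the noise field of each round) is drawn from a
#' substream derived from `config@masterSeed` and the image's `sourceId`, so
#' the result is independent of processing order and reproducible
#' bit-for-bit.
#'
#' @param image a [PestImage-class].
#' @param config a [CascadeConfig-class].
#' @return list of [PestImage-class] records of length
#'   `expansionFactor(config)`, each carrying the source label and a full
#'   transform chain.
#' @examples
#' img <- PestImage(array(rep(0:255, length.out = 48 * 48 * 3), c(48, 48, 3)), "AJ")
#' length(cascadeOne(img, CascadeConfig()))   # 16
#' @export
cascadeOne <- function(image, config = CascadeConfig()) {
  stopifnot(is(image, "PestImage"), is(config, "CascadeConfig"))
  validObject(config)
  out <- vector("list", expansionFactor(config))
  pos <- 0L
  for (round in seq_len(config@rounds)) {
    s <- deriveSeed(config@masterSeed,
                    paste0("cascade/", image@sourceId, "/round", round))
    withSeed(s, {
      thetas <- stats::runif(3, config@rotationRange[1], config@rotationRange[2])
      r1 <- rotateImage(image, thetas[1])
      r2 <- rotateImage(image, thetas[2])
      r3 <- rotateImage(image, thetas[3])
      enhanced <- equalizeHist(r2)
      noised <- addGaussianNoise(r3, sigma = config@noiseSigma,
                                 mean = config@noiseMean)
      out[[pos + 1L]] <- r1
      out[[pos + 2L]] <- enhanced
      out[[pos + 3L]] <- noised
      out[[pos + 4L]] <- scaleIn(enhanced, config@scaleZoom)
      out[[pos + 5L]] <- scaleIn(noised, config@scaleZoom)
    })
    pos <- pos + 5L
  }
  if (config@includeOriginal) out[[pos + 1L]] <- image
  out
}

#' Run the cascade over all images of one class
#'
#' @param images list of [PestImage-class] records sharing a single label, or
#'   a [PestImageSet-class] containing one class.
#' @param config a [CascadeConfig-class].
#' @return list of augmented records of length
#'   `length(images) * expansionFactor(config)`.
#' @export
augmentClass <- function(images, config = CascadeConfig()) {
  if (is(images, "PestImageSet")) images <- images@images
  stopifnot(is.list(images))
  if (length(images)) {
    labs <- unique(vapply(images, function(im) im@label, character(1)))
    if (length(labs) != 1L)
      stop(sprintf("augmentClass requires a single class; found: %s",
                   paste(labs, collapse = ", ")))
  }
  do.call(c, lapply(images, cascadeOne, config = config)) %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cascade over a full dataset
#'
#' Maps [augmentClass()] over every class. The class set is unchanged and
#' every per-class count is multiplied by `expansionFactor(config)`.
#'
#' @param dataset a [PestImageSet-class].
#' @param config a [CascadeConfig-class].
#' @return the augmented [PestImageSet-class].
#' @rdname augmentDataset
#' @export
setMethod("augmentDataset", signature("PestImageSet", "CascadeConfig"),
          function(dataset, config) {
  imgs <- list()
  for (cl in dataset@classes) {
    keep <- imageLabels(dataset) == cl
    imgs <- c(imgs, augmentClass(dataset@images[keep], config))
  }
  new("PestImageSet", images = imgs, classes = dataset@classes)
})
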
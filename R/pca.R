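# Fancy-PCA intensity augmentation: perturb images along the principal
# components of the RGB channel covariance, with per-component coefficients
# scaled by the eigenvalues (the AlexNet-style color perturbation).
#
# Covariance is estimated on unit-scaled intensities (pixel / 255) so that
# the perturbation magnitude is well conditioned on 8-bit images; the
# resulting shift is mapped back to the 0-255 scale before quantization.

# 3x3 channel covariance over all pixels of a list of PestImage, each
# resized to workingSide for estimation.
channelCovariance <- function(images, workingSide = 64L) {
  mats <- lapply(images, function(im) {
    px <- bilinearResize(im@pixels * 1.0, workingSide, workingSide) / 255
    matrix(px, ncol = 3)
  })
  X <- do.call(rbind, mats)
  stats::cov(X)
}

#' Number of principal components retaining a variance fraction
#'
#' Selects the smallest number of leading eigenvalues of a channel covariance
#' whose cumulative explained variance reaches `varianceThreshold`. With the
#' default threshold of 0.95, a dataset whose three channels are perfectly
#' correlated (a rank-1 covariance) yields `k = 1`; a threshold of 1 retains
#' the full component count.
#'
#' @param covariance a symmetric covariance matrix (3 x 3 for RGB), or a
#'   [PestImageSet-class] whose channel covariance is estimated first.
#' @param varianceThreshold fraction of total variance to retain, in (0, 1].
#' @return integer component count `k`.
#' @export
pcaComponentCount <- function(covariance, varianceThreshold = 0.95) {
  if (is(covariance, "PestImageSet")) {
    covariance <- channelCovariance(covariance@images)
  }
  if (!is.numeric(varianceThreshold) || varianceThreshold <= 0 ||
      varianceThreshold > 1)
    stop("varianceThreshold must lie in (0, 1]")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total <= 0)
    stop("degenerate channel covariance: zero total variance")
  k <- which(cumsum(ev) / total >= varianceThreshold - 1e-12)[1]
  as.integer(k)
}

# Shared perturbation core: given an eigendecomposition, add a single RGB
# shift P[, 1:k] %*% (alpha_j * lambda_j) to every pixel of the image.
pcaShiftImage <- function(image, eig, k, alphaSigma, seed) {
  draw <- function() stats::rnorm(k, mean = 0, sd = alphaSigma)
  alpha <- if (is.null(seed)) draw() else withSeed(seed, draw())
  shift <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    (alpha * eig$values[seq_len(k)])
  px <- image@pixels * 1.0
  for (ch in 1:3) px[, , ch] <- px[, , ch] + shift[ch] * 255
  res <- image
  res@pixels <- quantizePixels(px)
  appendChain(res, "pca_augment",
              list(k = k, alphaSigma = alphaSigma, seed = seed))
}

# Single-image fancy-PCA (fits on the image's own pixel covariance); the
# registered `pca_augment` transform for applyTransform().
pcaPerturbImage <- function(image, varianceThreshold = 0.95, alphaSigma = 0.1,
                            seed = NULL) {
  C <- stats::cov(matrix(image@pixels / 255, ncol = 3))
  eig <- eigen(C, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  if (sum(eig$values) <= 0)
    stop("degenerate channel covariance: the image is constant")
  k <- pcaComponentCount(C, varianceThreshold)
  pcaShiftImage(image, eig, k, alphaSigma, seed)
}

#' Fancy-PCA augmentation of a dataset
#'
#' Fits the 3 x 3 RGB channel covariance over all pixels of the dataset
#' (each image resized to a common working resolution for estimation),
#' retains the smallest number of principal components `k` whose cumulative
#' explained variance reaches `varianceThreshold`, and emits one perturbed
#' copy of every image: a single color shift
#' \eqn{\sum_{j \le k} p_j \, \alpha_j \lambda_j} with
#' \eqn{\alpha_j \sim N(0, \texttt{alphaSigma})}, applied to all pixels and
#' quantized. Labels are preserved; `alphaSigma = 0` returns exact copies.
#'
#' @param dataset a non-empty [PestImageSet-class].
#' @param varianceThreshold cumulative variance fraction to retain
#'   (default 0.95).
#' @param alphaSigma standard deviation of the perturbation coefficients
#'   (default 0.1).
#' @param workingSide square working resolution for covariance estimation
#'   (default 64); the perturbation itself is applied at native resolution.
#' @param seed integer master seed; each image draws from its own derived
#'   substream.
#' @return a [PestImageSet-class] of perturbed copies, one per input image.
#' @export
pcaAugment <- function(dataset, varianceThreshold = 0.95, alphaSigma = 0.1,
                       workingSide = 64L, seed = 1L) {
  stopifnot(is(dataset, "PestImageSet"))
  if (length(dataset@images) == 0L) stop("dataset must be non-empty")
  C <- channelCovariance(dataset@images, workingSide)
  eig <- eigen(C, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  if (sum(eig$values) <= 0)
    stop("degenerate channel covariance: dataset has zero pixel variance")
  k <- pcaComponentCount(C, varianceThreshold)
  out <- vector("list", length(dataset@images))
  for (i in seq_along(dataset@images)) {
    im <- dataset@images[[i]]
    s <- deriveSeed(seed, paste0("pca/", im@sourceId, "/", i))
    out[[i]] <- pcaShiftImage(im, eig, k, alphaSigma, s)
  }
  new("PestImageSet", images = out, classes = dataset@classes)
}
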
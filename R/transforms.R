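# Atomic label-preserving transforms.
#
# Every operator: (i) leaves the class label untouched, (ii) returns a raster
# of the same dimensions as its input, (iii) computes in double precision and
# quantizes once (round half away from zero, clip to [0, 255]), and
# (iv) appends one record to the image's transform chain.

appendChain <- function(img, name, params) {
  img@transformChain <- c(img@transformChain,
                          list(list(name = name, params = params)))
  img
}

#' Registered atomic transform names
#'
#' @return character vector of the transform names accepted by
#'   [TransformSpec()] and [applyTransform()].
#' @export
registeredTransforms <- function() {
  c("rotate", "flip_h", "flip_v", "gaussian_noise", "hist_equalize",
    "scale_in", "mixup", "pca_augment")
}

# Exact counterclockwise quarter-turn of a matrix, applied k times.
rot90mat <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    tm <- t(m)
    m <- tm[rev(seq_len(nrow(tm))), , drop = FALSE]
  }
  m
}

#' Rotate an image about its center
#'
#' Rotates the raster counterclockwise by `theta` degrees about the raster
#' center using the 2x2 rotation matrix
#' \eqn{R(\theta) = [\cos\theta, -\sin\theta; \sin\theta, \cos\theta]}.
#' The canvas size is unchanged. At multiples of 90 degrees on square rasters
#' the rotation is an exact pixel permutation; otherwise the output is
#' resampled by inverse mapping with the requested interpolation, and pixels
#' whose preimage falls outside the canvas are filled by symmetric reflection
#' (default) or a constant value. Reflection fill avoids the dark corner
#' wedges that constant fill would inject as spurious features.
#'
#' @param image a [PestImage-class].
#' @param theta rotation angle in degrees (finite; reduced modulo 360).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill `"reflect"` (default) or a single numeric constant in 0..255.
#' @return the rotated [PestImage-class]; same label, same dimensions.
#' @examples
#' img <- PestImage(array(seq_len(48) %% 256, c(4, 4, 3)), "AJ")
#' identical(pixelData(rotateImage(img, 0)), pixelData(img))
#' @export
rotateImage <- function(image, theta, interpolation = c("bilinear", "nearest"),
                        fill = "reflect") {
  stopifnot(is(image, "PestImage"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("theta must be a finite numeric scalar")
  interpolation <- match.arg(interpolation)
  theta <- theta %% 360
  px <- image@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  record <- list(theta = theta, interpolation = interpolation, fill = fill)

  if (theta %% 90 == 0 && (h == w || theta %% 180 == 0)) {
    k <- as.integer(theta / 90) %% 4L
    out <- px
    for (ch in 1:3) out[, , ch] <- rot90mat(px[, , ch], k)
    res <- image
    res@pixels <- out
    return(appendChain(res, "rotate", record))
  }

  rad <- theta * pi / 180
  ct <- cos(rad); st <- sin(rad)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  # output grid, center-relative, y-axis pointing up
  up <- rep(seq_len(w) - cc, each = h)
  vp <- rep(cr - seq_len(h), times = w)
  # inverse rotation R(-theta)
  u <- ct * up + st * vp
  v <- -st * up + ct * vp
  srcC <- cc + u
  srcR <- cr - v
  outside <- srcR < 0.5 | srcR > h + 0.5 | srcC < 0.5 | srcC > w + 0.5
  outF <- array(0, dim(px))
  for (ch in 1:3) {
    vals <- if (interpolation == "nearest") {
      rs <- reflectIndex(as.integer(roundHalfUp(srcR)), h)
      cs <- reflectIndex(as.integer(roundHalfUp(srcC)), w)
      px[, , ch][cbind(rs, cs)]
    } else {
      bilinearGather(px[, , ch], srcR, srcC)
    }
    if (is.numeric(fill)) vals[outside] <- fill
    outF[, , ch] <- matrix(vals, h, w)
  }
  res <- image
  res@pixels <- quantizePixels(outF)
  appendChain(res, "rotate", record)
}

#' Mirror an image across an axis
#'
#' A horizontal flip mirrors the image left-right (reverses columns); a
#' vertical flip mirrors it top-bottom (reverses rows). Both are exact pixel
#' permutations and involutions.
#'
#' @param image a [PestImage-class].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return the flipped [PestImage-class].
#' @export
flipImage <- function(image, axis = c("horizontal", "vertical")) {
  stopifnot(is(image, "PestImage"))
  axis <- match.arg(axis)
  px <- image@pixels
  out <- if (axis == "horizontal") {
    px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  } else {
    px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  }
  res <- image
  res@pixels <- out
  appendChain(res, if (axis == "horizontal") "flip_h" else "flip_v",
              list(axis = axis))
}

#' Inject additive Gaussian noise
#'
#' Adds an independent Gaussian draw to every pixel of every channel, then
#' quantizes. `sigma` is expressed on the 0-255 intensity scale.
#'
#' @param image a [PestImage-class].
#' @param sigma noise standard deviation (>= 0); default 10.
#' @param mean noise mean; default 0.
#' @param seed optional integer seed giving the draw its own substream.
#' @return the noised [PestImage-class].
#' @export
addGaussianNoise <- function(image, sigma = 10, mean = 0, seed = NULL) {
  stopifnot(is(image, "PestImage"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  px <- image@pixels
  draw <- function() stats::rnorm(length(px), mean = mean, sd = sigma)
  noise <- if (is.null(seed)) draw() else withSeed(seed, draw())
  res <- image
  res@pixels <- quantizePixels(px + noise)
  appendChain(res, "gaussian_noise",
              list(sigma = sigma, mean = mean, seed = seed))
}

# Equalize one channel vector of 0..255 integers; returns integers.
equalizeChannel <- function(v) {
  n <- length(v)
  tab <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(tab)
  cdfMin <- cdf[cdf > 0][1]
  if (n == cdfMin) return(v)  # constant channel: identity by convention
  map <- quantizePixels((cdf - cdfMin) / (n - cdfMin) * 255)
  map[v + 1L]
}

#' Per-channel histogram equalization
#'
#' Splits the RGB image into its three channels and equalizes each
#' independently with the cumulative-histogram formula
#' `out(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * 255)`, stretching the
#' intensity values over the full 8-bit range. The per-channel mapping is
#' monotone non-decreasing; a constant channel is returned unchanged (the
#' formula's denominator degenerates to zero there and identity is the only
#' label-safe convention).
#'
#' @param image a [PestImage-class].
#' @return the contrast-enhanced [PestImage-class].
#' @export
equalizeHist <- function(image) {
  stopifnot(is(image, "PestImage"))
  px <- image@pixels
  out <- px
  for (ch in 1:3) {
    m <- px[, , ch]
    out[, , ch] <- matrix(equalizeChannel(as.integer(m)), nrow(m), ncol(m))
  }
  res <- image
  res@pixels <- out
  appendChain(res, "hist_equalize", list())
}

#' Zoom in by central crop and resize
#'
#' Crops the central `floor(side / zoom)` window in each dimension and
#' bilinearly resizes it back to the original dimensions. `zoom = 1` is the
#' identity.
#'
#' @param image a [PestImage-class].
#' @param zoom central-crop zoom factor (>= 1); default 1.25.
#' @return the zoomed [PestImage-class]; dimensions unchanged.
#' @export
scaleIn <- function(image, zoom = 1.25) {
  stopifnot(is(image, "PestImage"))
  if (!is.numeric(zoom) || length(zoom) != 1L || zoom < 1)
    stop("zoom must be a numeric scalar >= 1")
  px <- image@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ch <- floor(h / zoom); cw <- floor(w / zoom)
  if (ch < 1 || cw < 1) stop("zoom crops the image below one pixel")
  if (ch == h && cw == w) {
    res <- image
    return(appendChain(res, "scale_in", list(zoom = zoom)))
  }
  r0 <- floor((h - ch) / 2) + 1
  c0 <- floor((w - cw) / 2) + 1
  crop <- px[r0:(r0 + ch - 1), c0:(c0 + cw - 1), , drop = FALSE]
  out <- bilinearResize(crop * 1.0, h, w)
  res <- image
  res@pixels <- quantizePixels(out)
  appendChain(res, "scale_in", list(zoom = zoom))
}

#' Zoom out by reflective padding and resize
#'
#' The complement of [scaleIn()]: pads the image symmetrically by reflection
#' so its content shrinks by `1 / zoom`, then resizes back to the original
#' dimensions. Used by the scale in/out benchmark strategy.
#'
#' @param image a [PestImage-class].
#' @param zoom zoom-out factor (>= 1); `zoom = 1` is the identity.
#' @return the zoomed-out [PestImage-class]; dimensions unchanged.
#' @export
scaleOut <- function(image, zoom = 1.25) {
  stopifnot(is(image, "PestImage"))
  if (!is.numeric(zoom) || length(zoom) != 1L || zoom < 1)
    stop("zoom must be a numeric scalar >= 1")
  px <- image@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ph <- ceiling(h * zoom); pw <- ceiling(w * zoom)
  if (ph == h && pw == w) {
    res <- image
    return(appendChain(res, "scale_out", list(zoom = zoom)))
  }
  padTop <- floor((ph - h) / 2); padLeft <- floor((pw - w) / 2)
  ri <- reflectIndex(seq_len(ph) - padTop, h)
  ci <- reflectIndex(seq_len(pw) - padLeft, w)
  padded <- px[ri, ci, , drop = FALSE]
  out <- bilinearResize(padded * 1.0, h, w)
  res <- image
  res@pixels <- quantizePixels(out)
  appendChain(res, "scale_out", list(zoom = zoom))
}

#' Mix two same-class images (mixup)
#'
#' Forms the per-pixel convex combination
#' \eqn{X' = \lambda X_i + (1 - \lambda) X_j} of two images of the same
#' class, with weight `lambda` on the first image. The shared label is
#' preserved; mixing images of different classes, or an image with itself, is
#' rejected. If the partner's dimensions differ it is bilinearly resized to
#' match the first image.
#'
#' @param first,second [PestImage-class] objects with the same label.
#' @param lambda mixing weight in `[0, 1]`; augmentation uses the open
#'   interval (the study setting is 0.2), the endpoints reduce to the inputs.
#' @return the mixed [PestImage-class].
#' @examples
#' a <- PestImage(array(100L, c(2, 2, 3)), "AJ", "a")
#' b <- PestImage(array(200L, c(2, 2, 3)), "AJ", "b")
#' pixelData(mixupImages(a, b, 0.2))[1, 1, 1]  # 180
#' @export
mixupImages <- function(first, second, lambda = 0.2) {
  stopifnot(is(first, "PestImage"), is(second, "PestImage"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a numeric scalar in [0, 1]")
  if (first@label != second@label)
    stop("mixup pairs must share the same class label")
  if (identical(first, second))
    stop("mixup requires two different records, not an image with itself")
  pa <- first@pixels * 1.0
  pb <- second@pixels * 1.0
  if (!identical(dim(pa)[1:2], dim(pb)[1:2])) {
    pb <- bilinearResize(pb, dim(pa)[1], dim(pa)[2])
  }
  res <- first
  res@pixels <- quantizePixels(lambda * pa + (1 - lambda) * pb)
  appendChain(res, "mixup",
              list(lambda = lambda, partner = second@sourceId))
}

#' Apply a registered transform by specification
#'
#' Dispatches a [TransformSpec-class] to the corresponding atomic operator.
#' The returned record keeps the input's label (label preservation), its
#' dimensions, and gains one transform-chain entry. Stochastic transforms use
#' `spec@seed` when set, so the same image, spec and seed give bit-identical
#' output. The `mixup` spec requires a `partner` [PestImage-class] in its
#' params; `pca_augment` here perturbs along the principal components of the
#' image's own channel covariance (see [pcaAugment()] for the dataset-level
#' fit).
#'
#' @param image a [PestImage-class].
#' @param spec a [TransformSpec-class].
#' @return the transformed [PestImage-class].
#' @export
applyTransform <- function(image, spec) {
  stopifnot(is(image, "PestImage"))
  if (is.character(spec)) spec <- TransformSpec(spec)
  stopifnot(is(spec, "TransformSpec"))
  validObject(spec)
  p <- spec@params
  seed <- if (is.na(spec@seed)) NULL else spec@seed
  switch(spec@name,
    rotate = rotateImage(image,
                         theta = if (is.null(p$theta)) 0 else p$theta,
                         interpolation = if (is.null(p$interpolation))
                           "bilinear" else p$interpolation,
                         fill = if (is.null(p$fill)) "reflect" else p$fill),
    flip_h = flipImage(image, "horizontal"),
    flip_v = flipImage(image, "vertical"),
    gaussian_noise = addGaussianNoise(image,
                                      sigma = if (is.null(p$sigma)) 10 else p$sigma,
                                      mean = if (is.null(p$mean)) 0 else p$mean,
                                      seed = seed),
    hist_equalize = equalizeHist(image),
    scale_in = scaleIn(image, zoom = if (is.null(p$zoom)) 1.25 else p$zoom),
    mixup = {
      if (is.null(p$partner)) stop("mixup spec requires a 'partner' image in params")
      mixupImages(image, p$partner,
                  lambda = if (is.null(p$lambda)) 0.2 else p$lambda)
    },
    pca_augment = pcaPerturbImage(image,
                                  varianceThreshold = if (is.null(p$varianceThreshold))
                                    0.95 else p$varianceThreshold,
                                  alphaSigma = if (is.null(p$alphaSigma))
                                    0.1 else p$alphaSigma,
                                  seed = seed),
    stop(sprintf("unknown transform '%s'", spec@name))
  )
}
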
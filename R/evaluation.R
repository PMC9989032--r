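# Desk-scale evaluation harness.
#
# The classifier mirrors the study protocol: a frozen convolutional feature
# backbone, flatten, then a trainable two-layer dense head (512 ReLU units
# with dropout 0.5, softmax output), optimized with minibatch Adam on
# categorical cross-entropy, validation accuracy recorded every epoch.
# The bundled `tiny` backbone is a seeded fixed random-convolution stack
# (two conv/mean-pool blocks) so the harness runs on one CPU with no deep
# learning framework; only the head ever trains, which matches the frozen
# backbone protocol. The vgg16/vgg19/resnet50 presets require pretrained
# weights that cannot be bundled and raise a capability error.

#' Classification accuracy
#'
#' Fraction of positionwise matches between predictions and truth:
#' correct predictions divided by total predictions.
#'
#' @param predictions character vector of predicted class labels.
#' @param truth character vector of true class labels, same length.
#' @return accuracy fraction in `[0, 1]`.
#' @examples
#' accuracyScore(c("a", "b", "b", "a"), c("a", "b", "a", "a"))  # 0.75
#' @export
accuracyScore <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth))
    stop("predictions and truth must be non-empty and of equal length")
  mean(predictions == truth)
}

#' Baseline-relative contribution percentage
#'
#' The relative improvement of an augmented-training run over the
#' no-augmentation baseline, `100 * (augmented - baseline) / baseline`,
#' truncated (not rounded) to two decimals. Truncation is deliberate: it is
#' the rule that reproduces the published two-decimal contribution figures
#' from the corresponding accuracies (82.182 vs 71.123 gives 15.54;
#' 76.713 vs 72.552 gives 5.73).
#'
#' @param augmentedAccuracy validation accuracy of the augmented run, in
#'   percent.
#' @param baselineAccuracy validation accuracy of the baseline run, in
#'   percent (> 0).
#' @return the contribution in percent, truncated to two decimals.
#' @examples
#' contributionPercent(82.182, 71.123)  # 15.54
#' @export
contributionPercent <- function(augmentedAccuracy, baselineAccuracy) {
  if (!is.numeric(baselineAccuracy) || baselineAccuracy <= 0)
    stop("baselineAccuracy must be positive")
  v <- 100 * (augmentedAccuracy - baselineAccuracy) / baselineAccuracy
  # guard against representation error just below an exact hundredth
  trunc(v * 100 + sign(v) * 1e-9) / 100
}

# --- tiny frozen backbone ---------------------------------------------------

# Patch matrix for a valid 3x3 convolution over an H x W x C array:
# rows are output pixels (column-major), columns the 9*C patch entries.
im2col3 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cch <- dim(x)[3]
  oh <- h - 2L; ow <- w - 2L
  cols <- vector("list", 9L * cch)
  k <- 0L
  for (ch in seq_len(cch)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        k <- k + 1L
        cols[[k]] <- as.vector(x[(1:oh) + di, (1:ow) + dj, ch])
      }
    }
  }
  matrix(unlist(cols, use.names = FALSE), ncol = 9L * cch)
}

# 2x2 mean pooling of an H x W x F array (floor division of dimensions).
meanPool2 <- function(x) {
  h <- 2L * (dim(x)[1] %/% 2L); w <- 2L * (dim(x)[2] %/% 2L)
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  (x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
   x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
   x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
   x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]) / 4
}

tinyBackboneWeights <- function(seed, filters1 = 8L, filters2 = 16L) {
  withSeed(seed, list(
    W1 = matrix(stats::rnorm(9L * 3L * filters1, sd = sqrt(2 / 27)),
                9L * 3L, filters1),
    W2 = matrix(stats::rnorm(9L * filters1 * filters2,
                             sd = sqrt(2 / (9 * filters1))),
                9L * filters1, filters2)
  ))
}

tinyFeatures <- function(px, bw) {
  x <- px / 255
  a1 <- im2col3(x) %*% bw$W1
  a1[a1 < 0] <- 0
  oh <- dim(x)[1] - 2L; ow <- dim(x)[2] - 2L
  p1 <- meanPool2(array(a1, c(oh, ow, ncol(bw$W1))))
  a2 <- im2col3(p1) %*% bw$W2
  a2[a2 < 0] <- 0
  oh2 <- dim(p1)[1] - 2L; ow2 <- dim(p1)[2] - 2L
  p2 <- meanPool2(array(a2, c(oh2, ow2, ncol(bw$W2))))
  as.vector(p2)
}

featureMatrix <- function(dataset, config, bw) {
  side <- config@inputSide
  n <- length(dataset@images)
  feats <- NULL
  for (i in seq_len(n)) {
    px <- bilinearResize(dataset@images[[i]]@pixels * 1.0, side, side)
    f <- tinyFeatures(px, bw)
    if (is.null(feats)) feats <- matrix(0, n, length(f))
    feats[i, ] <- f
  }
  feats
}

#' PestClassifier: a frozen backbone plus a trainable dense head
#'
#' @slot head the [HeadSpec-class].
#' @slot config the [TrainConfig-class].
#' @slot backbone list of frozen backbone weights.
#' @slot headWeights list of initialized head weights (`W1`, `b1`, `W2`,
#'   `b2`), set at build time and replaced by trained weights after
#'   [trainAndEvaluate()].
#' @slot featureDim integer backbone feature dimension.
#' @aliases PestClassifier
#' @exportClass PestClassifier
setClass("PestClassifier", representation(
  head = "HeadSpec",
  config = "TrainConfig",
  backbone = "list",
  headWeights = "list",
  featureDim = "integer"
))

initHead <- function(featureDim, head, seed) {
  withSeed(seed, list(
    W1 = matrix(stats::rnorm(featureDim * head@hiddenUnits,
                             sd = sqrt(2 / featureDim)),
                featureDim, head@hiddenUnits),
    b1 = rep(0, head@hiddenUnits),
    W2 = matrix(stats::rnorm(head@hiddenUnits * head@outputUnits,
                             sd = sqrt(1 / head@hiddenUnits)),
                head@hiddenUnits, head@outputUnits),
    b2 = rep(0, head@outputUnits)
  ))
}

#' Build the evaluation classifier
#'
#' Assembles a classifier from a frozen feature-extraction backbone, a
#' flatten step, and the modified fully connected head: a 512-unit
#' rectified-linear layer with dropout 0.5 followed by a softmax layer with
#' one unit per class. With the `tiny` backbone (the default) the feature
#' extractor is a seeded fixed two-block random-convolution stack suited to
#' CPU-scale experiments. The `vgg16`, `vgg19` and `resnet50` presets need
#' externally supplied pretrained convolutional weights and raise a
#' capability error here.
#'
#' @param head a [HeadSpec-class]; `outputUnits` must equal the number of
#'   classes of the datasets the classifier will see.
#' @param config a [TrainConfig-class]. Two builds with the same seed have
#'   identical initial weights.
#' @return a [PestClassifier-class].
#' @export
buildClassifier <- function(head, config = TrainConfig()) {
  stopifnot(is(head, "HeadSpec"), is(config, "TrainConfig"))
  validObject(head); validObject(config)
  if (config@backbone != "tiny")
    stop(sprintf(paste0("backbone '%s' requires pretrained weights that are ",
                        "not bundled with this package; use backbone 'tiny'"),
                 config@backbone))
  bw <- tinyBackboneWeights(deriveSeed(config@seed, "backbone"))
  side <- config@inputSide
  probe <- array(0, c(side, side, 3))
  featureDim <- length(tinyFeatures(probe, bw))
  hw <- initHead(featureDim, head, deriveSeed(config@seed, "head"))
  new("PestClassifier", head = head, config = config, backbone = bw,
      headWeights = hw, featureDim = as.integer(featureDim))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

headForward <- function(X, w) {
  H <- X %*% w$W1
  H <- sweep(H, 2, w$b1, "+")
  H[H < 0] <- 0
  Z <- H %*% w$W2
  sweep(Z, 2, w$b2, "+")
}

#' Class probabilities for a single image
#'
#' Forward pass of the classifier (no dropout): backbone features, then the
#' dense head with softmax output. Probabilities sum to 1.
#'
#' @param classifier a [PestClassifier-class].
#' @param image a [PestImage-class].
#' @return numeric probability vector of length `outputUnits`.
#' @export
predictProba <- function(classifier, image) {
  stopifnot(is(classifier, "PestClassifier"), is(image, "PestImage"))
  side <- classifier@config@inputSide
  px <- bilinearResize(image@pixels * 1.0, side, side)
  f <- tinyFeatures(px, classifier@backbone)
  if (!is.null(classifier@headWeights$featMean)) {
    f <- (f - classifier@headWeights$featMean) / classifier@headWeights$featSd
  }
  z <- headForward(matrix(f, 1), classifier@headWeights)
  as.vector(softmaxRows(z))
}

#' Train the head and record per-epoch accuracy curves
#'
#' Optimizes categorical cross-entropy over the dense head with minibatch
#' Adam at the configured learning rate and batch size, dropout 0.3 at the
#' backbone-head junction and 0.5 on the hidden layer, for the configured
#' number of epochs, recording training and validation accuracy after every
#' epoch. The backbone stays frozen throughout. Train and validation sets
#' must share the class set and be disjoint by source id: the provenance
#' guard rejects any training record (including augmented derivatives, which
#' inherit their source's id) whose source image is in the validation set.
#'
#' @param classifier a [PestClassifier-class] from [buildClassifier()].
#' @param train training [PestImageSet-class] (possibly augmented).
#' @param validation held-out [PestImageSet-class] of original images.
#' @param config a [TrainConfig-class]; defaults to the classifier's.
#' @return an [EvalResult-class] with per-epoch curves and the final
#'   validation accuracy.
#' @export
trainAndEvaluate <- function(classifier, train, validation,
                             config = classifier@config) {
  stopifnot(is(classifier, "PestClassifier"), is(train, "PestImageSet"),
            is(validation, "PestImageSet"))
  if (!setequal(train@classes, validation@classes))
    stop("train and validation sets must share the same class set")
  leak <- intersect(unique(sourceIds(train)), unique(sourceIds(validation)))
  if (length(leak))
    stop(sprintf("leakage: %d source image(s) appear in both train and validation (e.g. %s)",
                 length(leak), leak[1]))
  if (length(train@images) == 0L || length(validation@images) == 0L)
    stop("train and validation sets must be non-empty")

  classes <- train@classes
  Xtr <- featureMatrix(train, config, classifier@backbone)
  Xva <- featureMatrix(validation, config, classifier@backbone)
  mu <- colMeans(Xtr)
  sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-6)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xva <- sweep(sweep(Xva, 2, mu), 2, sdv, "/")
  ytr <- match(imageLabels(train), classes)
  yva <- match(imageLabels(validation), classes)

  w <- classifier@headWeights
  nTr <- nrow(Xtr)
  C <- classifier@head@outputUnits
  Ytr <- matrix(0, nTr, C); Ytr[cbind(seq_len(nTr), ytr)] <- 1

  adam <- lapply(w[c("W1", "b1", "W2", "b2")], function(p)
    list(m = p * 0, v = p * 0))
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  lr <- config@learningRate
  step <- 0L
  trainCurve <- numeric(config@epochs)
  valCurve <- numeric(config@epochs)

  withSeed(deriveSeed(config@seed, "training"), {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(nTr)
      for (start in seq(1, nTr, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, nTr)]
        X <- Xtr[idx, , drop = FALSE]
        Y <- Ytr[idx, , drop = FALSE]
        nb <- nrow(X)
        # input (junction) dropout
        if (config@dropoutInput > 0) {
          mIn <- matrix(stats::runif(length(X)) >= config@dropoutInput,
                        nb, ncol(X)) / (1 - config@dropoutInput)
          X <- X * mIn
        }
        H <- X %*% w$W1
        H <- sweep(H, 2, w$b1, "+")
        act <- H > 0
        H[!act] <- 0
        if (config@dropoutHead > 0) {
          mH <- matrix(stats::runif(length(H)) >= config@dropoutHead,
                       nb, ncol(H)) / (1 - config@dropoutHead)
          H <- H * mH
        }
        Z <- sweep(H %*% w$W2, 2, w$b2, "+")
        P <- softmaxRows(Z)
        dZ <- (P - Y) / nb
        gW2 <- crossprod(H, dZ)
        gb2 <- colSums(dZ)
        dH <- dZ %*% t(w$W2)
        if (config@dropoutHead > 0) dH <- dH * mH
        dH[!act] <- 0
        gW1 <- crossprod(X, dH)
        gb1 <- colSums(dH)

        step <- step + 1L
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        for (nm in names(grads)) {
          st <- adam[[nm]]
          st$m <- b1m * st$m + (1 - b1m) * grads[[nm]]
          st$v <- b2m * st$v + (1 - b2m) * grads[[nm]]^2
          adam[[nm]] <- st
          mh <- st$m / (1 - b1m^step)
          vh <- st$v / (1 - b2m^step)
          w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
      }
      predTr <- max.col(headForward(Xtr, w), ties.method = "first")
      predVa <- max.col(headForward(Xva, w), ties.method = "first")
      trainCurve[epoch] <- mean(predTr == ytr)
      valCurve[epoch] <- mean(predVa == yva)
    }
  })

  new("EvalResult", trainCurve = trainCurve, valCurve = valCurve,
      finalValAccuracy = valCurve[config@epochs], config = config)
}
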
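#' @import methods
NULL

#' PestImage: one labeled 8-bit RGB raster with provenance
#'
#' The atomic unit of the augmentation framework: an integer pixel array of
#' shape height x width x 3 with values in `[0, 255]`, a class label, the id
#' of the originating raw image, and an append-only chain of the transforms
#' (with parameters) applied since that source. Every transform in the
#' package preserves the label: the augmented image inherits the class of its
#' source unchanged.
#'
#' @slot pixels integer array, height x width x 3, values in 0..255.
#' @slot label character scalar class label.
#' @slot sourceId character scalar identifying the originating raw image.
#' @slot transformChain list of transform records, each a list with elements
#'   `name` and `params`; empty for an untransformed image.
#'
#' @aliases PestImage
#' @exportClass PestImage
setClass("PestImage", representation(
  pixels = "array",
  label = "character",
  sourceId = "character",
  transformChain = "list"
))

setValidity("PestImage", function(object) {
  px <- object@pixels
  d <- dim(px)
  if (length(d) != 3L) return("pixels must be a 3-D array (h x w x 3)")
  if (d[3] != 3L) return("pixels must have exactly 3 channels")
  if (d[1] < 1L || d[2] < 1L) return("pixels must have positive height and width")
  if (!is.integer(px)) return("pixels must have integer storage mode")
  if (anyNA(px)) return("pixels must not contain NA")
  if (min(px) < 0L || max(px) > 255L) return("pixel intensities must lie in [0, 255]")
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    return("label must be a non-empty character scalar")
  if (length(object@sourceId) != 1L || is.na(object@sourceId))
    return("sourceId must be a character scalar")
  for (entry in object@transformChain) {
    if (!is.list(entry) || is.null(entry$name))
      return("every transformChain entry must be a list with a 'name' element")
  }
  TRUE
})

#' Construct a PestImage
#'
#' @param pixels numeric or integer array of shape h x w x 3; numeric input
#'   is quantized (round half away from zero, clip) to 0..255.
#' @param label class label.
#' @param sourceId identifier of the originating raw image; defaults to an
#'   anonymous id.
#' @param transformChain list of prior transform records (default empty).
#' @return a validated [PestImage-class] object.
#' @examples
#' img <- PestImage(array(128L, c(4, 4, 3)), label = "AJ")
#' imageLabel(img)
#' @export
PestImage <- function(pixels, label, sourceId = "unnamed",
                      transformChain = list()) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (!is.integer(pixels)) pixels <- quantizePixels(pixels)
  new("PestImage", pixels = pixels, label = as.character(label),
      sourceId = as.character(sourceId), transformChain = transformChain)
}

#' PestImageSet: an ordered collection of labeled pest images
#'
#' Holds an ordered list of [PestImage-class] records over a fixed set of
#' classes. Images may have different native resolutions. Per-class counts
#' always sum to the total number of records, and every record's label is a
#' member of the class set.
#'
#' @slot images list of PestImage objects.
#' @slot classes character vector of class labels (the full class set, which
#'   may include classes with zero images).
#'
#' @aliases PestImageSet
#' @exportClass PestImageSet
setClass("PestImageSet", representation(
  images = "list",
  classes = "character"
))

setValidity("PestImageSet", function(object) {
  if (anyDuplicated(object@classes)) return("classes must be unique")
  for (im in object@images) {
    if (!is(im, "PestImage")) return("images must all be PestImage objects")
    if (!(im@label %in% object@classes))
      return(sprintf("record label '%s' is not in the class set", im@label))
  }
  TRUE
})

#' Construct a PestImageSet
#'
#' @param images list of [PestImage-class] objects.
#' @param classes character vector of class labels; defaults to the sorted
#'   unique labels found in `images`.
#' @return a validated [PestImageSet-class] object.
#' @export
PestImageSet <- function(images = list(), classes = NULL) {
  if (is(images, "PestImage")) images <- list(images)
  if (is.null(classes)) {
    classes <- sort(unique(vapply(images, function(im) im@label, character(1))))
  }
  new("PestImageSet", images = images, classes = as.character(classes))
}

#' TransformSpec: a named atomic transform with parameters
#'
#' Identifies one registered atomic transform (`rotate`, `flip_h`, `flip_v`,
#' `gaussian_noise`, `hist_equalize`, `scale_in`, `mixup`, `pca_augment`)
#' together with its parameters and an optional seed for its random draws.
#'
#' @slot name registered transform name.
#' @slot params named list of parameters for the transform.
#' @slot seed integer seed for stochastic transforms, or `NA`.
#'
#' @aliases TransformSpec
#' @exportClass TransformSpec
setClass("TransformSpec", representation(
  name = "character",
  params = "list",
  seed = "integer"
))

setValidity("TransformSpec", function(object) {
  if (length(object@name) != 1L) return("name must be a character scalar")
  if (!object@name %in% registeredTransforms())
    return(sprintf("unknown transform name '%s'; registered transforms: %s",
                   object@name, paste(registeredTransforms(), collapse = ", ")))
  TRUE
})

#' Construct a TransformSpec
#'
#' @param name registered transform name.
#' @param params named list of transform parameters.
#' @param seed optional integer seed for the transform's random draws.
#' @return a validated [TransformSpec-class] object.
#' @examples
#' spec <- TransformSpec("rotate", list(theta = 90))
#' @export
TransformSpec <- function(name, params = list(), seed = NA_integer_) {
  new("TransformSpec", name = name, params = params,
      seed = as.integer(seed))
}

#' CascadeConfig: parameters of the cascaded augmentation pipeline
#'
#' Configures the manipulation-based cascade. Each pass over a source image
#' draws three random center rotations; the first rotated copy is stored as
#' is, the second is histogram-equalized, the third receives Gaussian noise,
#' and both transformed copies are additionally scaled (central crop and
#' resize back), for five stored images per pass. With `rounds` passes and
#' the untouched original retained, one source image expands into
#' `5 * rounds + 1` images — 16 with the defaults, matching a 54-image class
#' expanding to 864.
#'
#' @slot rounds integer number of independent cascade passes per source image.
#' @slot rotationRange numeric length-2 degrees interval for the random
#'   rotation draws (default `[0, 360)`).
#' @slot noiseSigma Gaussian noise standard deviation on the 0-255 scale.
#' @slot noiseMean Gaussian noise mean.
#' @slot scaleZoom central-crop zoom factor (>= 1) for the scaling step.
#' @slot includeOriginal logical; append the untouched original to the output.
#' @slot masterSeed integer master seed; per-image substreams are derived
#'   from it so results are independent of processing order.
#'
#' @aliases CascadeConfig
#' @exportClass CascadeConfig
setClass("CascadeConfig", representation(
  rounds = "integer",
  rotationRange = "numeric",
  noiseSigma = "numeric",
  noiseMean = "numeric",
  scaleZoom = "numeric",
  includeOriginal = "logical",
  masterSeed = "integer"
))

setValidity("CascadeConfig", function(object) {
  if (object@rounds < 1L) return("rounds must be >= 1")
  if (length(object@rotationRange) != 2L ||
      object@rotationRange[2] < object@rotationRange[1])
    return("rotationRange must be an increasing length-2 interval")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@scaleZoom < 1) return("scaleZoom must be >= 1")
  TRUE
})

#' Construct a CascadeConfig
#'
#' @param rounds cascade passes per source image (default 3).
#' @param rotationRange degrees interval for random rotations
#'   (default `c(0, 360)`).
#' @param noiseSigma Gaussian noise standard deviation on the 0-255 scale
#'   (default 10).
#' @param noiseMean Gaussian noise mean (default 0).
#' @param scaleZoom central-crop zoom factor (default 1.25).
#' @param includeOriginal keep the untouched original (default TRUE).
#' @param masterSeed integer master seed (default 1).
#' @return a validated [CascadeConfig-class] object.
#' @examples
#' cfg <- CascadeConfig()
#' expansionFactor(cfg)   # 16
#' @export
CascadeConfig <- function(rounds = 3L, rotationRange = c(0, 360),
                          noiseSigma = 10, noiseMean = 0, scaleZoom = 1.25,
                          includeOriginal = TRUE, masterSeed = 1L) {
  new("CascadeConfig", rounds = as.integer(rounds),
      rotationRange = as.numeric(rotationRange),
      noiseSigma = noiseSigma, noiseMean = noiseMean, scaleZoom = scaleZoom,
      includeOriginal = includeOriginal, masterSeed = as.integer(masterSeed))
}

#' HeadSpec: the modified fully connected classification head
#'
#' The two-layer dense head appended to a frozen feature backbone: a 512-unit
#' rectified-linear layer with dropout 0.5, followed by a softmax layer with
#' one unit per class.
#'
#' @slot hiddenUnits integer hidden layer width (default 512).
#' @slot dropout dropout rate on the hidden layer (default 0.5).
#' @slot outputUnits integer number of classes.
#'
#' @aliases HeadSpec
#' @exportClass HeadSpec
setClass("HeadSpec", representation(
  hiddenUnits = "integer",
  dropout = "numeric",
  outputUnits = "integer"
))

setValidity("HeadSpec", function(object) {
  if (object@hiddenUnits < 1L) return("hiddenUnits must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  if (object@outputUnits < 2L) return("outputUnits must be >= 2")
  TRUE
})

#' Construct a HeadSpec
#'
#' @param outputUnits number of classes.
#' @param hiddenUnits hidden layer width (default 512).
#' @param dropout hidden-layer dropout rate (default 0.5).
#' @return a validated [HeadSpec-class] object.
#' @export
HeadSpec <- function(outputUnits, hiddenUnits = 512L, dropout = 0.5) {
  new("HeadSpec", hiddenUnits = as.integer(hiddenUnits), dropout = dropout,
      outputUnits = as.integer(outputUnits))
}

#' TrainConfig: training protocol for the evaluation harness
#'
#' Training hyperparameters mirroring the study protocol: Adam at learning
#' rate 0.001, batch size 32, categorical cross-entropy, dropout between 0.3
#' (backbone-head junction) and 0.5 (hidden layer), validation every epoch.
#' The `tiny` backbone is a frozen seeded random-convolution feature
#' extractor bundled for CPU-scale experiments; `vgg16`, `vgg19` and
#' `resnet50` presets set the published input sides (224, 224, 124) but
#' require externally supplied pretrained weights and raise a capability
#' error in this package.
#'
#' @slot epochs integer training epochs.
#' @slot learningRate Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot dropoutHead dropout on the 512-unit hidden layer.
#' @slot dropoutInput dropout at the backbone-head junction.
#' @slot backbone one of `tiny`, `vgg16`, `vgg19`, `resnet50`.
#' @slot inputSide square input side in pixels fed to the backbone.
#' @slot seed integer seed controlling weight init, dropout and batching.
#'
#' @aliases TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  epochs = "integer",
  learningRate = "numeric",
  batchSize = "integer",
  dropoutHead = "numeric",
  dropoutInput = "numeric",
  backbone = "character",
  inputSide = "integer",
  seed = "integer"
))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!object@backbone %in% c("tiny", "vgg16", "vgg19", "resnet50"))
    return("backbone must be one of tiny, vgg16, vgg19, resnet50")
  if (object@inputSide < 8L) return("inputSide must be >= 8")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs training epochs (default 100, the published protocol;
#'   desk-scale runs use fewer).
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size (default 32).
#' @param dropoutHead hidden-layer dropout (default 0.5).
#' @param dropoutInput junction dropout (default 0.3).
#' @param backbone feature backbone preset (default `"tiny"`).
#' @param inputSide input side in pixels; defaults to the backbone's preset
#'   (32 tiny, 224 VGG16/VGG19, 124 ResNet50).
#' @param seed integer seed (default 1).
#' @return a validated [TrainConfig-class] object.
#' @examples
#' cfg <- TrainConfig(epochs = 20, backbone = "tiny")
#' @export
TrainConfig <- function(epochs = 100L, learningRate = 0.001, batchSize = 32L,
                        dropoutHead = 0.5, dropoutInput = 0.3,
                        backbone = "tiny", inputSide = NULL, seed = 1L) {
  if (is.null(inputSide)) {
    inputSide <- switch(backbone, tiny = 32L, vgg16 = 224L, vgg19 = 224L,
                        resnet50 = 124L, 32L)
  }
  new("TrainConfig", epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), dropoutHead = dropoutHead,
      dropoutInput = dropoutInput, backbone = backbone,
      inputSide = as.integer(inputSide), seed = as.integer(seed))
}

#' EvalResult: per-epoch accuracy curves and summary accuracy
#'
#' Output of [trainAndEvaluate()]: train and validation accuracy recorded
#' every epoch, the final validation accuracy (fraction of correct
#' predictions), and a snapshot of the training configuration.
#'
#' @slot trainCurve numeric per-epoch training accuracy.
#' @slot valCurve numeric per-epoch validation accuracy.
#' @slot finalValAccuracy final validation accuracy in `[0, 1]`.
#' @slot config the [TrainConfig-class] used.
#'
#' @aliases EvalResult
#' @exportClass EvalResult
setClass("EvalResult", representation(
  trainCurve = "numeric",
  valCurve = "numeric",
  finalValAccuracy = "numeric",
  config = "TrainConfig"
))

setValidity("EvalResult", function(object) {
  if (length(object@trainCurve) != length(object@valCurve))
    return("train and validation curves must have equal length")
  acc <- c(object@trainCurve, object@valCurve, object@finalValAccuracy)
  if (any(acc < 0 | acc > 1)) return("accuracies must lie in [0, 1]")
  TRUE
})
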
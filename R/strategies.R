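# The eleven benchmark augmentation strategies: baseline set 0 (no
# augmentation) through the proposed cascaded pipeline (set 10), as named
# reproducible presets. Atomic strategies emit a fixed per-image fan-out
# (two new images per source, except deterministic contrast enhancement,
# which has a single distinct output) and retain the originals, so the
# benchmark datasets are comparable in size.

strategyTable <- function() {
  data.frame(
    id = 0:10,
    name = c("No augmentation", "Rotation", "Vertical + horizontal flips",
             "Contrast enhancement", "Noise", "PCA", "Mixup", "Scale in/out",
             "Rotation + scaling", "Rotation + flip + scaling",
             "Proposed approach"),
    stringsAsFactors = FALSE)
}

#' The registered augmentation strategy presets
#'
#' @return data frame with columns `id` (0-10) and `name`, one row per
#'   registered strategy.
#' @export
strategyPresets <- function() strategyTable()

# fan-out helper: apply f(image, draw) for draws 1..fanout under derived seeds
fanOut <- function(images, seed, tag, fanout, f) {
  out <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    for (j in seq_len(fanout)) {
      s <- deriveSeed(seed, sprintf("%s/%s/%d/%d", tag, im@sourceId, i, j))
      out <- c(out, list(withSeed(s, f(im))))
    }
  }
  out
}

sameClassPartner <- function(images, i) {
  labs <- vapply(images, function(im) im@label, character(1))
  pool <- setdiff(which(labs == labs[i]), i)
  if (length(pool) == 0L)
    stop(sprintf("mixup needs at least two images of class '%s'", labs[i]))
  images[[pool[sample.int(length(pool), 1L)]]]
}

#' Build one benchmark augmentation strategy
#'
#' Materializes the augmented dataset of the requested strategy preset:
#'
#' * 0 — no augmentation (the dataset is returned record for record);
#' * 1 — random center rotations with the benchmark angle range 0-150 degrees;
#' * 2 — vertical and horizontal flips;
#' * 3 — contrast enhancement (per-channel histogram equalization);
#' * 4 — Gaussian noise injection;
#' * 5 — fancy-PCA perturbation at 95% retained variance;
#' * 6 — same-class mixup with weight 0.2;
#' * 7 — scale in / scale out (central-crop zoom and reflective-pad shrink);
#' * 8 — rotation followed by scaling;
#' * 9 — rotation, a random flip, then scaling;
#' * 10 — the proposed cascaded pipeline at its defaults.
#'
#' Strategies 1-9 retain the original records (controllable via
#' `includeOriginal`) and add a fixed fan-out of derived records per source;
#' strategy 10 delegates to [augmentDataset()], whose default configuration
#' already retains the originals. Every derived record keeps its source
#' label.
#'
#' @param dataset a [PestImageSet-class].
#' @param id strategy id in 0..10.
#' @param seed integer seed controlling all random draws.
#' @param fanout derived records per source for strategies 1-9 (default 2).
#' @param includeOriginal keep the source records in the output for
#'   strategies 1-9 (default TRUE).
#' @return the augmented [PestImageSet-class].
#' @examples
#' d <- syntheticPestSet(counts = c(AJ = 3, SO = 3), size = 48)
#' nImages(buildStrategy(d, 1, seed = 7))   # 3+3 originals + 2 per source
#' @export
buildStrategy <- function(dataset, id, seed = 1L, fanout = 2L,
                          includeOriginal = TRUE) {
  stopifnot(is(dataset, "PestImageSet"))
  if (!is.numeric(id) || length(id) != 1L || !id %in% 0:10)
    stop("strategy id must be an integer in 0..10")
  id <- as.integer(id)
  if (id == 0L) return(dataset)
  if (length(dataset@images) == 0L) stop("dataset must be non-empty")
  imgs <- dataset@images

  derived <- switch(as.character(id),
    "1" = fanOut(imgs, seed, "rot", fanout, function(im)
      rotateImage(im, stats::runif(1, 0, 150))),
    "2" = unlist(lapply(imgs, function(im)
      list(flipImage(im, "vertical"), flipImage(im, "horizontal"))),
      recursive = FALSE),
    "3" = lapply(imgs, equalizeHist),
    "4" = fanOut(imgs, seed, "noise", fanout, function(im)
      addGaussianNoise(im, sigma = 10)),
    "5" = {
      sets <- lapply(seq_len(fanout), function(j)
        pcaAugment(dataset, varianceThreshold = 0.95,
                   seed = deriveSeed(seed, paste0("pca/", j)))@images)
      unlist(sets, recursive = FALSE)
    },
    "6" = {
      out <- list()
      for (i in seq_along(imgs)) {
        for (j in seq_len(fanout)) {
          s <- deriveSeed(seed, sprintf("mixup/%d/%d", i, j))
          out <- c(out, list(withSeed(s, {
            partner <- sameClassPartner(imgs, i)
            mixupImages(imgs[[i]], partner, lambda = 0.2)
          })))
        }
      }
      out
    },
    "7" = unlist(lapply(imgs, function(im)
      list(scaleIn(im, 1.25), scaleOut(im, 1.25))), recursive = FALSE),
    "8" = fanOut(imgs, seed, "rotscale", fanout, function(im)
      scaleIn(rotateImage(im, stats::runif(1, 0, 150)), 1.25)),
    "9" = fanOut(imgs, seed, "rotflipscale", fanout, function(im) {
      r <- rotateImage(im, stats::runif(1, 0, 150))
      f <- flipImage(r, if (stats::runif(1) < 0.5) "horizontal" else "vertical")
      scaleIn(f, 1.25)
    }),
    "10" = NULL)

  if (id == 10L) {
    return(augmentDataset(dataset, CascadeConfig(masterSeed = seed)))
  }
  all <- if (includeOriginal) c(imgs, derived) else derived
  new("PestImageSet", images = all, classes = dataset@classes)
}

#' Compare augmentation strategies by validation accuracy
#'
#' Runs the benchmark comparison: the dataset is split 7:3 (stratified,
#' without any overlap of records); for each requested strategy id the
#' training portion is augmented by that strategy, the evaluation classifier
#' is trained on the augmented output, and accuracy is measured on the
#' held-out unmodified validation images. Because every strategy is applied
#' to the training portion only, no augmented derivative of a validation
#' image ever enters training (this provenance guard is also enforced inside
#' [trainAndEvaluate()]).
#'
#' @param dataset a non-empty [PestImageSet-class] of original images.
#' @param ids integer vector of strategy ids in 0..10.
#' @param config a [TrainConfig-class] for the evaluation classifier.
#' @param seed integer seed controlling the split and all augmentation and
#'   training randomness.
#' @return data frame with one row per id: `id`, `name`, `nTrain`,
#'   `valAccuracy` (fraction in `[0, 1]`).
#' @export
runComparison <- function(dataset, ids, config = TrainConfig(epochs = 20L),
                          seed = 1L) {
  stopifnot(is(dataset, "PestImageSet"))
  if (length(dataset@images) == 0L) stop("dataset must be non-empty")
  if (length(ids) == 0L || !all(ids %in% 0:10))
    stop("ids must be a non-empty subset of 0..10")
  split <- splitTrainVal(dataset, 0.7, stratified = TRUE,
                         seed = deriveSeed(seed, "comparison/split"))
  tab <- strategyTable()
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- as.integer(ids[i])
    trainSet <- buildStrategy(split$train, id,
                              seed = deriveSeed(seed, paste0("strategy/", id)))
    cfg <- config
    cfg@seed <- deriveSeed(seed, paste0("train/", id))
    clf <- buildClassifier(HeadSpec(outputUnits = length(dataset@classes)), cfg)
    res <- trainAndEvaluate(clf, trainSet, split$validation, cfg)
    rows[[i]] <- data.frame(id = id, name = tab$name[tab$id == id],
                            nTrain = length(trainSet@images),
                            valAccuracy = finalValAccuracy(res),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
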
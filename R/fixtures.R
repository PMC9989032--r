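# Seeded procedural generator of labeled pest-like images.
#
# The generator emulates the STRUCTURE of a small curated castor insect-pest
# photo collection — six classes, imbalanced counts (54/84/49/69/72/44,
# total 372), class-distinguishable color/shape/texture — not pest
# morphology. Each image is a textured foliage-like background plus one
# elliptical "pest" body whose hue, elongation, spot texture and background
# palette come from the class archetype, with per-seed jitter in position,
# orientation, scale and hue.

#' Class archetypes of the synthetic pest fixtures
#'
#' Returns the six default archetypes, keyed by the class abbreviations of
#' the castor pest collection (AJ castor semilooper, SO Bihar hairy
#' caterpillar, EF leafhopper, RS thrips, TR whitefly, LR leaf miner). Each
#' archetype fixes a base body color (RGB, 0-255), an ellipse elongation
#' (`bodyAspect`), a body size as a fraction of the image side, a spot
#' texture density, and a background palette; the archetypes are pairwise
#' distinguishable by at least one parameter so a trivial classifier can
#' separate the classes.
#'
#' @return named list of archetype parameter lists.
#' @export
classArchetypes <- function() {
  list(
    AJ = list(name = "AJ", bodyHue = c(115, 125, 60), bodyAspect = 3.0,
              bodySize = 0.45, spotDensity = 0.15,
              bgColor = c(70, 130, 60), bgRange = 25),
    SO = list(name = "SO", bodyHue = c(80, 55, 40), bodyAspect = 2.4,
              bodySize = 0.42, spotDensity = 0.55,
              bgColor = c(95, 140, 55), bgRange = 30),
    EF = list(name = "EF", bodyHue = c(150, 205, 95), bodyAspect = 2.0,
              bodySize = 0.32, spotDensity = 0.05,
              bgColor = c(120, 165, 90), bgRange = 20),
    RS = list(name = "RS", bodyHue = c(45, 40, 50), bodyAspect = 4.0,
              bodySize = 0.30, spotDensity = 0.10,
              bgColor = c(85, 150, 70), bgRange = 25),
    TR = list(name = "TR", bodyHue = c(235, 235, 222), bodyAspect = 1.3,
              bodySize = 0.28, spotDensity = 0.08,
              bgColor = c(55, 110, 50), bgRange = 20),
    LR = list(name = "LR", bodyHue = c(210, 190, 70), bodyAspect = 1.6,
              bodySize = 0.34, spotDensity = 0.40,
              bgColor = c(150, 175, 95), bgRange = 30)
  )
}

# Smooth low-frequency field: coarse Gaussian grid bilinearly upsampled.
smoothField <- function(size, coarse = 8L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  arr <- array(g, c(coarse, coarse, 3))
  arr[, , 2] <- g; arr[, , 3] <- g
  bilinearResize(arr, size, size)[, , 1]
}

#' Generate one synthetic pest image
#'
#' Draws a deterministic (per archetype, size and seed) labeled RGB image:
#' a foliage-toned background with low-frequency mottling and fine grain,
#' plus one elliptical body with archetype-controlled hue, elongation and
#' spot texture, jittered in position (within the central 40% of the frame),
#' orientation (uniform over the circle), scale (+/-20%) and hue (+/-8%).
#'
#' @param archetype one of the names returned by [classArchetypes()], or an
#'   archetype parameter list.
#' @param size square image side in pixels (>= 32; default 128).
#' @param seed integer seed; same (archetype, size, seed) gives bit-identical
#'   images.
#' @param sourceId identifier stored on the record; defaults to
#'   `"<class>_seed<seed>"`.
#' @return a [PestImage-class] labeled with the archetype name.
#' @export
generatePestImage <- function(archetype, size = 128L, seed = 1L,
                              sourceId = NULL) {
  if (is.character(archetype)) {
    arcs <- classArchetypes()
    if (!archetype %in% names(arcs))
      stop(sprintf("unknown archetype '%s'", archetype))
    archetype <- arcs[[archetype]]
  }
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32 pixels")
  if (is.null(sourceId)) sourceId <- sprintf("%s_seed%d", archetype$name, seed)

  px <- withSeed(as.integer(seed), {
    mottle <- smoothField(size)
    grain <- matrix(stats::rnorm(size * size, sd = 5), size, size)
    out <- array(0, c(size, size, 3))
    for (ch in 1:3) {
      out[, , ch] <- archetype$bgColor[ch] + archetype$bgRange * mottle + grain
    }

    # body geometry: jittered center, orientation, scale
    cx <- size / 2 + stats::runif(1, -0.2, 0.2) * size
    cy <- size / 2 + stats::runif(1, -0.2, 0.2) * size
    ang <- stats::runif(1, 0, 2 * pi)
    len <- archetype$bodySize * size * stats::runif(1, 0.8, 1.2) / 2
    wid <- len / archetype$bodyAspect
    hueJit <- stats::runif(3, 0.92, 1.08)

    xs <- rep(seq_len(size), each = size) - cx
    ys <- rep(seq_len(size), times = size) - cy
    u <- cos(ang) * xs + sin(ang) * ys
    v <- -sin(ang) * xs + cos(ang) * ys
    d2 <- (u / len)^2 + (v / wid)^2
    inside <- d2 <= 1
    edge <- pmax(0, 1 - d2)  # shading toward the rim

    for (ch in 1:3) {
      body <- archetype$bodyHue[ch] * hueJit[ch] * (0.75 + 0.25 * edge)
      m <- out[, , ch]
      m[inside] <- body[inside]
      out[, , ch] <- m
    }

    # spot texture on the body
    nSpots <- round(archetype$spotDensity * 60)
    if (nSpots > 0) {
      idx <- which(matrix(inside, size, size), arr.ind = TRUE)
      if (nrow(idx) > 0) {
        pick <- idx[sample.int(nrow(idx), min(nSpots, nrow(idx))), , drop = FALSE]
        dark <- stats::runif(nrow(pick)) < 0.7
        rad <- 2L
        for (s in seq_len(nrow(pick))) {
          rr <- max(1, pick[s, 1] - rad):min(size, pick[s, 1] + rad)
          cc <- max(1, pick[s, 2] - rad):min(size, pick[s, 2] + rad)
          delta <- if (dark[s]) -60 else 45
          for (ch in 1:3) out[rr, cc, ch] <- out[rr, cc, ch] + delta
        }
      }
    }
    out
  })

  PestImage(px, label = archetype$name, sourceId = sourceId)
}

#' Generate a synthetic six-class pest dataset
#'
#' Builds a labeled dataset with the requested per-class image counts. The
#' defaults reproduce the structure of the curated castor pest collection:
#' classes AJ, SO, EF, RS, TR, LR with 54, 84, 49, 69, 72 and 44 images
#' (372 in total). Every image is drawn from its own substream derived from
#' `seed`, so the dataset is reproducible and independent of generation
#' order.
#'
#' @param counts named integer vector of per-class counts; names must be
#'   archetype names. Default: the curated-collection counts.
#' @param size square image side in pixels (default 128).
#' @param seed integer master seed (default 1).
#' @return a [PestImageSet-class] with exactly the requested counts.
#' @examples
#' d <- syntheticPestSet(counts = c(AJ = 2, SO = 3), size = 48, seed = 1)
#' classCounts(d)
#' @export
syntheticPestSet <- function(counts = c(AJ = 54, SO = 84, EF = 49,
                                        RS = 69, TR = 72, LR = 44),
                             size = 128L, seed = 1L) {
  arcs <- classArchetypes()
  if (is.null(names(counts)) || !all(names(counts) %in% names(arcs)))
    stop(sprintf("counts must be named with archetype names (%s)",
                 paste(names(arcs), collapse = ", ")))
  if (any(counts < 0)) stop("counts must be non-negative")
  imgs <- list()
  for (cl in names(counts)) {
    for (j in seq_len(counts[[cl]])) {
      s <- deriveSeed(seed, sprintf("fixture/%s/%d", cl, j))
      id <- sprintf("%s_%03d", cl, j)
      imgs <- c(imgs, list(generatePestImage(arcs[[cl]], size = size, seed = s,
                                             sourceId = id)))
    }
  }
  new("PestImageSet", images = imgs, classes = names(counts))
}
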
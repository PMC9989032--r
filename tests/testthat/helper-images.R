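# Deterministic in-code fixtures used across the suite.

# Small deterministic gradient image (no RNG).
gradientImage <- function(label = "AJ", size = 8L, sourceId = "grad") {
  px <- array(seq_len(size * size * 3) %% 256, c(size, size, 3))
  PestImage(px, label = label, sourceId = sourceId)
}

# Constant-value image.
constantImage <- function(value, label = "AJ", size = 4L, sourceId = "const") {
  PestImage(array(as.integer(value), c(size, size, 3)), label = label,
            sourceId = sourceId)
}

# Seeded random-content image (uniform noise).
noiseImage <- function(label = "AJ", size = 16L, seed = 1L,
                       sourceId = paste0("noise", seed)) {
  px <- withr::with_seed(seed, array(stats::runif(size * size * 3) * 255,
                                     c(size, size, 3)))
  PestImage(px, label = label, sourceId = sourceId)
}

# Two-class linearly separable set: class "red" around (200, 70, 70),
# class "blue" around (70, 70, 200), iid pixel noise. Mean color alone
# separates the classes, so a trained head should near-perfectly classify.
separableSet <- function(nPerClass = 30L, size = 48L, seed = 1L) {
  mk <- function(base, label, j) {
    px <- withr::with_seed(
      deriveSeed(seed, paste0("sep/", label, "/", j)),
      array(rep(base, each = size * size) +
              stats::rnorm(size * size * 3, sd = 15), c(size, size, 3)))
    PestImage(px, label = label, sourceId = sprintf("%s_%02d", label, j))
  }
  imgs <- c(
    lapply(seq_len(nPerClass), function(j) mk(c(200, 70, 70), "red", j)),
    lapply(seq_len(nPerClass), function(j) mk(c(70, 70, 200), "blue", j))
  )
  PestImageSet(imgs, classes = c("red", "blue"))
}

# One spec instance per registered transform, applicable to a single image.
specForTransform <- function(name, partner = NULL) {
  switch(name,
    rotate = TransformSpec("rotate", list(theta = 33)),
    flip_h = TransformSpec("flip_h"),
    flip_v = TransformSpec("flip_v"),
    gaussian_noise = TransformSpec("gaussian_noise", list(sigma = 12), seed = 7L),
    hist_equalize = TransformSpec("hist_equalize"),
    scale_in = TransformSpec("scale_in", list(zoom = 1.3)),
    mixup = TransformSpec("mixup", list(partner = partner, lambda = 0.2)),
    pca_augment = TransformSpec("pca_augment", seed = 7L)
  )
}
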
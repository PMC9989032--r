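# Internal numeric helpers shared by all transforms.
#
# Every operator computes in double precision and quantizes on output with a
# single rule (round half away from zero, clip to [0, 255]) so that results
# are bit-reproducible across platforms.

#' Quantize a floating-point raster to 8-bit integers
#'
#' Rounds half away from zero and clips to `[0, 255]`. All transform outputs
#' pass through this single rule so pixel values are reproducible bit-for-bit.
#'
#' @param x numeric array or matrix.
#' @return integer array of the same shape with values in 0..255.
#' @keywords internal
quantizePixels <- function(x) {
  q <- sign(x) * floor(abs(x) + 0.5)
  q <- pmin(pmax(q, 0), 255)
  storage.mode(q) <- "integer"
  q
}

# Symmetric (mirror-at-edge) reflection of arbitrary 1-based indices into
# 1..n: ... 2 1 | 1 2 ... n | n n-1 ...
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j >= n, 2 * n - 1 - j, j)
  as.integer(j + 1)
}

# Clamp 1-based fractional coordinates to the valid range.
clampCoord <- function(x, n) pmin(pmax(x, 1), n)

# Bilinear sampling of one channel matrix at fractional (row, col) positions.
# Out-of-range coordinates are handled by the caller (reflect or clamp).
bilinearGather <- function(mat, rs, cs) {
  n <- nrow(mat); m <- ncol(mat)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0;   fc <- cs - c0
  r0i <- reflectIndex(r0, n); r1i <- reflectIndex(r0 + 1, n)
  c0i <- reflectIndex(c0, m); c1i <- reflectIndex(c0 + 1, m)
  v00 <- mat[cbind(r0i, c0i)]; v01 <- mat[cbind(r0i, c1i)]
  v10 <- mat[cbind(r1i, c0i)]; v11 <- mat[cbind(r1i, c1i)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Bilinear resize of an h x w x 3 numeric array to newH x newW.
# Destination pixel centers map to source coordinates by
# src = (dst - 0.5) * (S / D) + 0.5, which is the exact identity when S == D.
bilinearResize <- function(px, newH, newW) {
  h <- dim(px)[1]; w <- dim(px)[2]
  if (newH == h && newW == w) return(px)
  rs <- clampCoord((seq_len(newH) - 0.5) * (h / newH) + 0.5, h)
  cs <- clampCoord((seq_len(newW) - 0.5) * (w / newW) + 0.5, w)
  rg <- rep(rs, times = newW)
  cg <- rep(cs, each = newH)
  out <- array(0, dim = c(newH, newW, dim(px)[3]))
  for (ch in seq_len(dim(px)[3])) {
    out[, , ch] <- matrix(bilinearGather(px[, , ch], rg, cg), newH, newW)
  }
  out
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus an arbitrary string key (for example a source-image
#' id and a transform index) to an integer seed below 2^31. Each
#' (seed, key) pair gets its own independent substream, so augmentation
#' results do not depend on iteration order.
#'
#' @param master integer master seed.
#' @param key character scalar naming the substream.
#' @return a single integer seed.
#' @export
deriveSeed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  p <- 2147483647
  h <- 5381
  for (b in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 33 + b) %% p
  }
  s <- (h + (abs(master) %% p) * 69069) %% p
  as.integer(if (s == 0) 1 else s)
}

# Run code with a locally derived RNG seed, restoring global RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Round half up (used for split sizes; base round() is round-half-even).
roundHalfUp <- function(x) floor(x + 0.5)
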
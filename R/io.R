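# Image-folder datasets: class-per-subdirectory folders of 8-bit RGB rasters,
# with a provenance manifest CSV. PNG is the canonical on-disk format because
# augmented pixels must round-trip bit-exactly; JPEG/TIFF/BMP are accepted on
# input through EBImage when it is installed.

readRaster <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    arr <- png::readPNG(file)
  } else if (ext %in% c("jpg", "jpeg", "bmp", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop(sprintf("reading %s files requires the EBImage package: %s",
                   ext, file))
    img <- EBImage::readImage(file)
    arr <- aperm(EBImage::imageData(img), c(2, 1, 3)[seq_len(length(dim(img)))])
  } else {
    stop(sprintf("cannot decode image file (unsupported extension): %s", file))
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  quantizePixels(arr * 255)
}

#' Load a class-per-subdirectory image folder
#'
#' Reads every decodable raster under the immediate subdirectories of `path`;
#' each subdirectory name becomes a class label. Records are ordered
#' lexicographically by class directory, then file name, so loading is
#' deterministic. If a `manifest.csv` written by [writeDataset()] is present
#' at the folder root, source ids and transform chains are restored from it;
#' otherwise the source id is the file's path relative to `path`.
#'
#' @param path directory whose immediate subdirectories are class names.
#' @return a [PestImageSet-class].
#' @export
loadImageFolder <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path))
  classDirs <- sort(list.dirs(path, recursive = FALSE))
  if (length(classDirs) == 0L) stop(sprintf("no class subdirectories in %s", path))

  manifest <- NULL
  mf <- file.path(path, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  }

  imgs <- list()
  classes <- basename(classDirs)
  for (d in classDirs) {
    files <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg|bmp|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      warning(sprintf("class directory '%s' contains no images", basename(d)))
      next
    }
    for (f in files) {
      rel <- file.path(basename(d), basename(f))
      srcId <- rel
      chain <- list()
      if (!is.null(manifest)) {
        row <- match(rel, manifest$file)
        if (!is.na(row)) {
          srcId <- manifest$source_id[row]
          tc <- manifest$transform_chain[row]
          if (!is.null(tc) && !is.na(tc) && nzchar(tc)) {
            chain <- jsonlite::fromJSON(tc, simplifyVector = FALSE)
          }
        }
      }
      imgs <- c(imgs, list(PestImage(readRaster(f), label = basename(d),
                                     sourceId = srcId,
                                     transformChain = chain)))
    }
  }
  new("PestImageSet", images = imgs, classes = classes)
}

#' Write a dataset as an image folder with a provenance manifest
#'
#' Writes one PNG per record under `path/<class>/`, plus a `manifest.csv`
#' with columns `file`, `class`, `source_id`, `transform_chain` (a JSON
#' serialization of the applied transforms) and `seed`. The written folder
#' round-trips losslessly through [loadImageFolder()] (pixel-exact,
#' label-exact, order-preserving for class-ordered datasets).
#'
#' @param dataset a [PestImageSet-class].
#' @param path output directory.
#' @param overwrite allow writing into an existing non-empty directory
#'   (default FALSE).
#' @param seed optional seed recorded in the manifest's `seed` column.
#' @return (invisibly) the manifest data frame.
#' @export
writeDataset <- function(dataset, path, overwrite = FALSE, seed = NA_integer_) {
  stopifnot(is(dataset, "PestImageSet"))
  if (dir.exists(path) && length(list.files(path)) > 0 && !overwrite)
    stop(sprintf("directory %s exists and is not empty (use overwrite = TRUE)",
                 path))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  counters <- stats::setNames(rep(0L, length(dataset@classes)), dataset@classes)
  rows <- vector("list", length(dataset@images))
  for (i in seq_along(dataset@images)) {
    im <- dataset@images[[i]]
    cl <- im@label
    counters[cl] <- counters[cl] + 1L
    dir.create(file.path(path, cl), showWarnings = FALSE)
    fname <- sprintf("%05d.png", counters[cl])
    rel <- file.path(cl, fname)
    png::writePNG(im@pixels / 255, file.path(path, rel))
    rows[[i]] <- data.frame(
      file = rel, class = cl, source_id = im@sourceId,
      transform_chain = if (length(im@transformChain))
        as.character(jsonlite::toJSON(im@transformChain, auto_unbox = TRUE,
                                      null = "null")) else "",
      seed = seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- data.frame(file = character(), class = character(),
                           source_id = character(),
                           transform_chain = character(), seed = integer())
  utils::write.csv(manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Stratified train/validation split
#'
#' Partitions a dataset into disjoint train and validation subsets without
#' any overlap of records. Under stratification (the default) each class
#' contributes `round(trainFraction * n)` records (round half up) to the
#' training set, so a 7:3 split of a 10-image class yields 7 train and 3
#' validation images and the stratification error is at most one record per
#' class. The union of the two subsets recovers the input exactly.
#'
#' @param dataset a [PestImageSet-class].
#' @param trainFraction fraction of records assigned to training, in (0, 1);
#'   default 0.7.
#' @param stratified split within each class (default TRUE); every class then
#'   needs at least 2 records.
#' @param seed integer seed; the same seed always gives the same partition.
#' @return list with elements `train` and `validation`, both
#'   [PestImageSet-class] over the input's class set.
#' @export
splitTrainVal <- function(dataset, trainFraction = 0.7, stratified = TRUE,
                          seed = 1L) {
  stopifnot(is(dataset, "PestImageSet"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  labs <- imageLabels(dataset)
  n <- length(labs)
  trainIdx <- integer(0)
  if (stratified) {
    for (cl in dataset@classes) {
      idx <- which(labs == cl)
      if (length(idx) == 0L) next
      if (length(idx) < 2L)
        stop(sprintf("class '%s' has fewer than 2 records; cannot stratify", cl))
      k <- as.integer(roundHalfUp(trainFraction * length(idx)))
      k <- min(max(k, 1L), length(idx) - 1L)  # both sides non-empty per class
      s <- deriveSeed(seed, paste0("split/", cl))
      pick <- withSeed(s, sample(idx, k))
      trainIdx <- c(trainIdx, pick)
    }
  } else {
    k <- as.integer(roundHalfUp(trainFraction * n))
    trainIdx <- withSeed(deriveSeed(seed, "split/all"), sample.int(n, k))
  }
  trainIdx <- sort(trainIdx)
  valIdx <- setdiff(seq_len(n), trainIdx)
  list(
    train = new("PestImageSet", images = dataset@images[trainIdx],
                classes = dataset@classes),
    validation = new("PestImageSet", images = dataset@images[valIdx],
                     classes = dataset@classes)
  )
}

#' Bilinearly resize an image to a square side
#'
#' Resizes to `side x side x 3` with bilinear interpolation. Model presets
#' use 224 pixels for the VGG16/VGG19 input and 124 for ResNet50; the tiny
#' desk-scale backbone uses 32. Resizing to the current size leaves pixels
#' untouched.
#'
#' @param image a [PestImage-class].
#' @param side target side in pixels (>= 1).
#' @return the resized [PestImage-class].
#' @export
resizeImage <- function(image, side) {
  stopifnot(is(image, "PestImage"))
  side <- as.integer(side)
  if (is.na(side) || side < 1L) stop("side must be >= 1")
  d <- dim(image@pixels)
  if (d[1] == side && d[2] == side) return(image)
  res <- image
  res@pixels <- quantizePixels(bilinearResize(image@pixels * 1.0, side, side))
  appendChain(res, "resize", list(side = side))
}
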
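# Accessors, subsetting and show methods for the core containers.

#' Accessors for PestImage
#'
#' `pixelData` returns the integer h x w x 3 pixel array, `imageLabel` the
#' class label, `sourceId` the originating raw-image id, and
#' `transformChain` the append-only list of applied transforms.
#'
#' @param x a [PestImage-class].
#' @return the corresponding slot value.
#' @name PestImage-accessors
#' @aliases pixelData imageLabel sourceId transformChain
NULL

#' @rdname PestImage-accessors
#' @export
setMethod("pixelData", "PestImage", function(x) x@pixels)

#' @rdname PestImage-accessors
#' @export
setMethod("imageLabel", "PestImage", function(x) x@label)

#' @rdname PestImage-accessors
#' @export
setMethod("sourceId", "PestImage", function(x) x@sourceId)

#' @rdname PestImage-accessors
#' @export
setMethod("transformChain", "PestImage", function(x) x@transformChain)

#' @export
setMethod("show", "PestImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PestImage %dx%d label=%s source=%s transforms=%d\n",
              d[1], d[2], object@label, object@sourceId,
              length(object@transformChain)))
})

#' @export
setMethod("dim", "PestImage", function(x) dim(x@pixels))

#' Accessors for PestImageSet
#'
#' `nImages` returns the number of records, `classNames` the ordered class
#' set, `classCounts` a named integer vector of per-class record counts
#' (including zero counts), `imageLabels` the per-record labels in order, and
#' `sourceIds` the per-record source ids.
#'
#' @param x a [PestImageSet-class].
#' @return see the per-function description.
#' @name PestImageSet-accessors
#' @aliases nImages classNames classCounts imageLabels sourceIds
NULL

#' @rdname PestImageSet-accessors
#' @export
setMethod("nImages", "PestImageSet", function(x) length(x@images))

#' @rdname PestImageSet-accessors
#' @export
setMethod("classNames", "PestImageSet", function(x) x@classes)

#' @rdname PestImageSet-accessors
#' @export
setMethod("imageLabels", "PestImageSet", function(x)
  vapply(x@images, function(im) im@label, character(1)))

#' @rdname PestImageSet-accessors
#' @export
setMethod("sourceIds", "PestImageSet", function(x)
  vapply(x@images, function(im) im@sourceId, character(1)))

#' @rdname PestImageSet-accessors
#' @export
setMethod("classCounts", "PestImageSet", function(x) {
  labs <- imageLabels(x)
  counts <- vapply(x@classes, function(cl) sum(labs == cl), integer(1))
  names(counts) <- x@classes
  counts
})

#' @export
setMethod("length", "PestImageSet", function(x) length(x@images))

#' @export
setMethod("show", "PestImageSet", function(object) {
  cc <- classCounts(object)
  cat(sprintf("PestImageSet with %d images over %d classes\n",
              length(object@images), length(object@classes)))
  if (length(cc)) {
    cat(paste(sprintf("  %s: %d", names(cc), cc), collapse = "\n"), "\n")
  }
})

#' @export
setMethod("[", "PestImageSet", function(x, i, j, ..., drop = TRUE) {
  new("PestImageSet", images = x@images[i], classes = x@classes)
})

#' @export
setMethod("[[", "PestImageSet", function(x, i) x@images[[i]])

#' Concatenate image sets
#'
#' @param x,... [PestImageSet-class] objects to combine; the class set is
#'   the union in first-seen order.
#' @return a combined [PestImageSet-class].
#' @export
setMethod("c", "PestImageSet", function(x, ...) {
  sets <- c(list(x), list(...))
  imgs <- do.call(c, lapply(sets, function(s) s@images))
  cls <- unique(unlist(lapply(sets, function(s) s@classes)))
  new("PestImageSet", images = imgs, classes = cls)
})

#' Subset a dataset to the records of one class
#'
#' @param x a [PestImageSet-class].
#' @param class a class label present in `classNames(x)`.
#' @return a [PestImageSet-class] restricted to that class (the class set is
#'   unchanged).
#' @export
classSubset <- function(x, class) {
  stopifnot(is(x, "PestImageSet"))
  if (!class %in% x@classes) stop(sprintf("unknown class '%s'", class))
  keep <- imageLabels(x) == class
  new("PestImageSet", images = x@images[keep], classes = x@classes)
}

#' @export
setMethod("show", "CascadeConfig", function(object) {
  cat(sprintf(paste0("CascadeConfig: rounds=%d rotation=[%g,%g) sigma=%g ",
                     "zoom=%g includeOriginal=%s seed=%d (expansion x%d)\n"),
              object@rounds, object@rotationRange[1], object@rotationRange[2],
              object@noiseSigma, object@scaleZoom, object@includeOriginal,
              object@masterSeed, expansionFactor(object)))
})

#' @export
setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: %d epochs, final validation accuracy %.4f\n",
              length(object@valCurve), object@finalValAccuracy))
})

#' Accessors for EvalResult
#'
#' @param x an [EvalResult-class].
#' @return `trainCurve`/`valCurve` return per-epoch accuracies;
#'   `finalValAccuracy` the final validation accuracy in `[0, 1]`.
#' @name EvalResult-accessors
NULL

#' @rdname EvalResult-accessors
#' @export
trainCurve <- function(x) x@trainCurve

#' @rdname EvalResult-accessors
#' @export
valCurve <- function(x) x@valCurve

#' @rdname EvalResult-accessors
#' @export
finalValAccuracy <- function(x) x@finalValAccuracy
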
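#' @rdname PestImage-accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname PestImage-accessors
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))

#' @rdname PestImage-accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname PestImage-accessors
#' @export
setGeneric("transformChain", function(x) standardGeneric("transformChain"))

#' @rdname PestImageSet-accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname PestImageSet-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname PestImageSet-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname PestImageSet-accessors
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname PestImageSet-accessors
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname expansionFactor
#' @export
setGeneric("expansionFactor", function(config) standardGeneric("expansionFactor"))

#' @rdname augmentDataset
#' @export
setGeneric("augmentDataset",
           function(dataset, config) standardGeneric("augmentDataset"))
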
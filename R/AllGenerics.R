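#' @title Accessor generics for SIM stacks
#' @description Dimension, pixel-size and data accessors shared by
#'   [RawSIMStack] and [ReconStack] objects.
#' @param x a stack object
#' @return the requested slot value (counts as integers, pixel sizes in
#'   micrometres, data as a numeric array)
#' @name stack-accessors
NULL

#' @rdname stack-accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname stack-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname stack-accessors
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname stack-accessors
#' @export
setGeneric("nZSlices", function(x) standardGeneric("nZSlices"))

#' @rdname stack-accessors
#' @export
setGeneric("nAngles", function(x) standardGeneric("nAngles"))

#' @rdname stack-accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname stack-accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname stack-accessors
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))

#' @rdname stack-accessors
#' @export
setGeneric("pixelSizeZ", function(x) standardGeneric("pixelSizeZ"))

#' @rdname stack-accessors
#' @export
setGeneric("fullRange", function(x) standardGeneric("fullRange"))

#' Crop a stack to a region
#'
#' @param x a [RawSIMStack] or [ReconStack]
#' @param region a [CropRegion]; for a `ReconStack` the lateral bounds are
#'   doubled automatically so that raw and reconstructed data can be cropped
#'   to the same physical boundaries.
#' @return a stack of the same class restricted to the region
#' @export
setGeneric("cropStack", function(x, region) standardGeneric("cropStack"))
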
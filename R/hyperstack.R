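## Constructors, accessors and plane-sequence utilities for SIM hyperstacks.

#' Construct a RawSIMStack
#'
#' Builds a raw SIM hyperstack either from a 7-D array
#' `(y, x, c, p, z, a, t)` or from a plane sequence (3-D array `(y, x, n)` or
#' list of matrices) together with explicit dimension counts. The plane
#' sequence is interpreted in canonical CPZAT order (channel fastest); use
#' [reorderToCPZAT()] first for data in a different order.
#'
#' @param data 7-D array, 3-D plane-sequence array, or list of Y-by-X matrices
#' @param dims named integer vector `c(C=, P=, Z=, A=, T=)`; required when
#'   `data` is a plane sequence
#' @param bitDepth camera bit depth (default 16)
#' @param pixelXY,pixelZ pixel sizes in micrometres; defaults (0.08, 0.125)
#'   are typical raw 3D-SIM voxel sizes and are used when metadata is absent
#' @return a [RawSIMStack]
#' @examples
#' s <- RawSIMStack(array(1, c(8, 8, 1, 5, 3, 3, 1)), bitDepth = 15)
#' nPhases(s)
#' @export
RawSIMStack <- function(data, dims = NULL, bitDepth = 16,
                        pixelXY = 0.08, pixelZ = 0.125) {
  if (is.list(data))
    data <- array(unlist(data), c(dim(data[[1]]), length(data)))
  if (length(dim(data)) == 3L) {
    if (is.null(dims))
      stop("dims = c(C=, P=, Z=, A=, T=) required for a plane sequence")
    dims <- dims[c("C", "P", "Z", "A", "T")]
    if (anyNA(dims)) stop("dims must name C, P, Z, A and T")
    if (prod(dims) != dim(data)[3L])
      stop("plane count ", dim(data)[3L], " does not match C*P*Z*A*T = ",
           prod(dims))
    dim(data) <- c(dim(data)[1:2], unname(dims))
  }
  new("RawSIMStack", data = data, bitDepth = bitDepth,
      pixelXY = pixelXY, pixelZ = pixelZ)
}

#' Construct a ReconStack
#'
#' @param data 5-D array `(y, x, c, z, t)`, or 3-D `(y, x, z)` for a
#'   single-channel single-timepoint stack
#' @param pixelXY,pixelZ pixel sizes in micrometres (reconstructed lateral
#'   pixels are half the raw size; default 0.04, 0.125)
#' @param fullRange FALSE if negative/below-mode intensities were clipped
#'   upstream (several checks will warn)
#' @return a [ReconStack]
#' @export
ReconStack <- function(data, pixelXY = 0.04, pixelZ = 0.125,
                       fullRange = TRUE) {
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L], 1L)
  new("ReconStack", data = data, pixelXY = pixelXY, pixelZ = pixelZ,
      fullRange = fullRange)
}

#' @rdname stack-accessors
#' @export
setMethod("stackData", "RawSIMStack", function(x) x@data)
#' @rdname stack-accessors
#' @export
setMethod("stackData", "ReconStack", function(x) x@data)
#' @rdname stack-accessors
#' @export
setMethod("nChannels", "RawSIMStack", function(x) dim(x@data)[3L])
#' @rdname stack-accessors
#' @export
setMethod("nChannels", "ReconStack", function(x) dim(x@data)[3L])
#' @rdname stack-accessors
#' @export
setMethod("nPhases", "RawSIMStack", function(x) dim(x@data)[4L])
#' @rdname stack-accessors
#' @export
setMethod("nZSlices", "RawSIMStack", function(x) dim(x@data)[5L])
#' @rdname stack-accessors
#' @export
setMethod("nZSlices", "ReconStack", function(x) dim(x@data)[4L])
#' @rdname stack-accessors
#' @export
setMethod("nAngles", "RawSIMStack", function(x) dim(x@data)[6L])
#' @rdname stack-accessors
#' @export
setMethod("nTimepoints", "RawSIMStack", function(x) dim(x@data)[7L])
#' @rdname stack-accessors
#' @export
setMethod("nTimepoints", "ReconStack", function(x) dim(x@data)[5L])
#' @rdname stack-accessors
#' @export
setMethod("bitDepth", "RawSIMStack", function(x) x@bitDepth)
#' @rdname stack-accessors
#' @export
setMethod("pixelSizeXY", "RawSIMStack", function(x) x@pixelXY)
#' @rdname stack-accessors
#' @export
setMethod("pixelSizeXY", "ReconStack", function(x) x@pixelXY)
#' @rdname stack-accessors
#' @export
setMethod("pixelSizeZ", "RawSIMStack", function(x) x@pixelZ)
#' @rdname stack-accessors
#' @export
setMethod("pixelSizeZ", "ReconStack", function(x) x@pixelZ)
#' @rdname stack-accessors
#' @export
setMethod("fullRange", "ReconStack", function(x) x@fullRange)

setMethod("show", "RawSIMStack", function(object) {
  d <- dim(object@data)
  cat("RawSIMStack:", d[2], "x", d[1], "px,",
      sprintf("C=%d P=%d Z=%d A=%d T=%d", d[3], d[4], d[5], d[6], d[7]),
      sprintf("(%d planes)\n", prod(d[3:7])))
  cat("  bit depth:", object@bitDepth,
      " pixel: ", object@pixelXY, "x", object@pixelZ, "um\n")
  cat("  intensity range: [", min(object@data), ",", max(object@data), "]\n")
})

setMethod("show", "ReconStack", function(object) {
  d <- dim(object@data)
  cat("ReconStack:", d[2], "x", d[1], "px,",
      sprintf("C=%d Z=%d T=%d", d[3], d[4], d[5]),
      if (object@fullRange) "(full range)\n" else "(range clipped!)\n")
  cat("  pixel: ", object@pixelXY, "x", object@pixelZ, "um",
      "  intensity range: [", signif(min(object@data), 6), ",",
      signif(max(object@data), 6), "]\n")
})

#' Extract one plane from a raw stack
#'
#' @param x a [RawSIMStack]
#' @param c,p,z,a,t 1-based channel, phase, z, angle and time indices
#' @return a Y-by-X matrix
#' @export
getPlane <- function(x, c = 1L, p = 1L, z = 1L, a = 1L, t = 1L) {
  x@data[, , c, p, z, a, t]
}

#' Flatten a raw stack to its CPZAT plane sequence
#'
#' @param x a [RawSIMStack]
#' @return a 3-D array `(y, x, plane)` with channel varying fastest, then
#'   phase, z, angle, time
#' @export
planeSequence <- function(x) {
  d <- dim(x@data)
  array(x@data, c(d[1], d[2], prod(d[3:7])))
}

#' Reorder a plane sequence into canonical CPZAT order
#'
#' Vendor platforms store the per-plane dimensions (channel, phase, z-slice,
#' angle, time) in different orders; all checks assume the canonical CPZAT
#' sequence, channel varying fastest. Given the source ordering (fastest
#' axis first) this permutes the planes bijectively into CPZAT order.
#'
#' @param planes 3-D array `(y, x, n)` or list of Y-by-X matrices in source
#'   order
#' @param sourceOrder a [DimensionOrder], or a 5-letter string such as
#'   `"PZCAT"`, or a preset name from [dimensionOrderPresets()]
#' @param dims named counts `c(C=, P=, Z=, A=, T=)`
#' @param ... further arguments (`bitDepth`, `pixelXY`, `pixelZ`) passed to
#'   [RawSIMStack()]
#' @return a [RawSIMStack] in canonical order
#' @examples
#' pl <- array(rep(0:3, each = 4), c(2, 2, 4))  # planes labelled 0..3
#' s <- reorderToCPZAT(pl, "ZPCAT", c(C = 1, P = 2, Z = 2, A = 1, T = 1))
#' planeSequence(s)[1, 1, ]  # 0 2 1 3
#' @export
reorderToCPZAT <- function(planes, sourceOrder, dims, ...) {
  if (is.list(planes))
    planes <- array(unlist(planes), c(dim(planes[[1]]), length(planes)))
  ord <- asDimensionOrder(sourceOrder)
  letters5 <- strsplit(ord@order, "")[[1]]
  dims <- dims[c("C", "P", "Z", "A", "T")]
  if (anyNA(dims)) stop("dims must name C, P, Z, A and T")
  n <- prod(dims)
  if (dim(planes)[3L] != n)
    stop("plane count ", dim(planes)[3L],
         " does not match C*P*Z*A*T = ", n)
  srcSizes <- dims[letters5]
  ## decompose each source index (0-based, fastest-first mixed radix), then
  ## recompose in CPZAT order
  j <- 0:(n - 1L)
  coord <- matrix(0L, n, 5L, dimnames = list(NULL, letters5))
  rem <- j
  for (k in seq_len(5L)) {
    coord[, k] <- rem %% srcSizes[k]
    rem <- rem %/% srcSizes[k]
  }
  C <- dims[["C"]]; P <- dims[["P"]]; Z <- dims[["Z"]]; A <- dims[["A"]]
  target <- coord[, "C"] +
    C * (coord[, "P"] + P * (coord[, "Z"] + Z * (coord[, "A"] +
                                                   A * coord[, "T"])))
  out <- planes
  out[, , target + 1L] <- planes[, , seq_len(n)]
  RawSIMStack(out, dims = dims, ...)
}

asDimensionOrder <- function(x) {
  if (is(x, "DimensionOrder")) return(x)
  x <- as.character(x)
  presets <- dimensionOrderPresets()
  if (tolower(x) %in% names(presets)) x <- presets[[tolower(x)]]
  new("DimensionOrder", order = toupper(x))
}

#' Dimension-order presets
#'
#' Editable presets mapping platform names to plane-sequence orderings
#' (fastest-varying axis first), read from
#' `inst/extdata/dimension-orders.json`. The canonical ordering is
#' `"omx" = "CPZAT"`. The shipped `"zeiss"` and `"nikon"` entries are
#' placeholders to be verified against the actual export of those platforms;
#' edit the JSON file (or pass an explicit order string) as needed.
#'
#' @return named list of 5-letter order strings
#' @export
dimensionOrderPresets <- function() {
  path <- system.file("extdata", "dimension-orders.json", package = "simqc")
  if (!nzchar(path)) return(list(omx = "CPZAT"))
  jsonlite::fromJSON(path)
}

#' Construct a crop region
#'
#' @param x0,x1,y0,y1,z0,z1 0-based half-open bounds (see [CropRegion])
#' @return a [CropRegion]
#' @export
cropRegion <- function(x0, x1, y0, y1, z0, z1) {
  new("CropRegion", x0 = as.integer(x0), x1 = as.integer(x1),
      y0 = as.integer(y0), y1 = as.integer(y1),
      z0 = as.integer(z0), z1 = as.integer(z1))
}

#' @rdname cropStack
#' @export
setMethod("cropStack", "RawSIMStack", function(x, region) {
  d <- dim(x@data)
  checkBounds(region, d[2], d[1], d[5])
  initialize(x, data = x@data[(region@y0 + 1L):region@y1,
                              (region@x0 + 1L):region@x1, , ,
                              (region@z0 + 1L):region@z1, , , drop = FALSE])
})

#' @rdname cropStack
#' @export
setMethod("cropStack", "ReconStack", function(x, region) {
  d <- dim(x@data)
  r2 <- cropRegion(2L * region@x0, 2L * region@x1,
                   2L * region@y0, 2L * region@y1, region@z0, region@z1)
  checkBounds(r2, d[2], d[1], d[4])
  initialize(x, data = x@data[(r2@y0 + 1L):r2@y1,
                              (r2@x0 + 1L):r2@x1, ,
                              (r2@z0 + 1L):r2@z1, , drop = FALSE])
})

checkBounds <- function(region, X, Y, Z) {
  if (region@x1 > X || region@y1 > Y || region@z1 > Z)
    stop("crop region exceeds stack bounds (", X, " x ", Y, " x ", Z, ")")
  invisible(TRUE)
}
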
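## Multi-page TIFF input/output for SIM hyperstacks.
##
## Integer (8/16-bit) pages go through the `tiff` package. Full-range
## reconstructed data are 32-bit float with negative values, which `tiff`
## (and EBImage) clamp to [0, 1] on both read and write; those pages are
## handled by a small built-in codec for uncompressed little/big-endian
## TIFF (single- or multi-strip, uint8/16/32 and float32 samples).
## Dimension metadata travels in a JSON sidecar (`<file>.json`).

TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
         photometric = 262L, stripOffsets = 273L, rowsPerStrip = 278L,
         stripByteCounts = 279L, sampleFormat = 339L)

## ---- minimal reader (uncompressed TIFF, any endianness) ----

readTiffPlanes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  endian <- if (identical(hdr[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(hdr[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  u16 <- function() readBin(con, "integer", 1L, 2L, signed = FALSE, endian = endian)
  u32 <- function() readBin(con, "integer", 1L, 4L, endian = endian)
  magic <- readBin(hdr[3:4], "integer", 1L, 2L, signed = FALSE,
                   endian = endian)
  if (magic != 42L) stop("bad TIFF magic in ", path)
  nextIFD <- u32()
  planes <- list()
  while (nextIFD != 0L) {
    seek(con, nextIFD)
    nEntries <- u16()
    tags <- list()
    for (i in seq_len(nEntries)) {
      tag <- u16(); type <- u16(); count <- u32()
      valPos <- seek(con)                      # 4-byte value/offset field
      size <- c(1L, 1L, 2L, 4L, 8L)[min(type, 5L)]
      if (size * count > 4L) { off <- u32(); seek(con, off) }
      vals <- switch(as.character(type),
        `3` = readBin(con, "integer", count, 2L, signed = FALSE, endian = endian),
        `4` = readBin(con, "integer", count, 4L, endian = endian),
        `1` = as.integer(readBin(con, "raw", count)),
        readBin(con, "raw", size * count))     # ignored types
      seek(con, valPos + 4L)
      tags[[as.character(tag)]] <- vals
    }
    nextIFD <- u32()
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TAG[[id]])]]
      if (is.null(v)) default else v
    }
    comp <- g("compression", 1L)
    if (comp != 1L)
      stop("only uncompressed TIFF is supported by the built-in reader; ",
           "got compression scheme ", comp)
    w <- g("width"); h <- g("length")
    bits <- g("bits", 1L)[1L]
    sf <- g("sampleFormat", 1L)[1L]
    offs <- g("stripOffsets"); counts <- g("stripByteCounts")
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      n <- counts[s] %/% (bits %/% 8L)
      piece <- if (sf == 3L) {
        if (bits != 32L) stop("only 32-bit float samples supported")
        readBin(con, "numeric", n, 4L, endian = endian)
      } else if (bits == 8L) {
        as.numeric(readBin(con, "raw", n))
      } else if (bits == 16L) {
        readBin(con, "integer", n, 2L, signed = FALSE, endian = endian)
      } else if (bits == 32L) {
        v <- as.numeric(readBin(con, "integer", n, 4L, endian = endian))
        v[v < 0] <- v[v < 0] + 2^32          # uint32 read through signed
        v
      } else stop("unsupported bits per sample: ", bits)
      vals <- c(vals, as.numeric(piece))
    }
    if (length(vals) != w * h)
      stop("TIFF strip payload does not match page dimensions")
    planes[[length(planes) + 1L]] <- matrix(vals, h, w, byrow = TRUE)
  }
  planes
}

## ---- minimal float32 writer (uncompressed, little-endian, one strip) ----

writeFloatTiff <- function(planes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  writeBin(as.raw(c(0x49, 0x49)), con); u16(42L)
  nPages <- length(planes)
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  bytesPerPage <- 4L * w * h
  ifdSize <- 2L + 9L * 12L + 4L
  dataStart <- 8L
  ifdStart <- dataStart + nPages * bytesPerPage
  u32(ifdStart)                                 # first IFD offset
  for (p in planes) {
    if (nrow(p) != h || ncol(p) != w) stop("pages must share dimensions")
    writeBin(as.numeric(t(p)), con, 4L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count); u32(value)
  }
  for (k in seq_len(nPages)) {
    u16(9L)                                     # entry count
    entry(TAG[["width"]], 4L, 1L, w)
    entry(TAG[["length"]], 4L, 1L, h)
    entry(TAG[["bits"]], 3L, 1L, 32L)
    entry(TAG[["compression"]], 3L, 1L, 1L)
    entry(TAG[["photometric"]], 3L, 1L, 1L)
    entry(TAG[["stripOffsets"]], 4L, 1L, dataStart + (k - 1L) * bytesPerPage)
    entry(TAG[["rowsPerStrip"]], 4L, 1L, h)
    entry(TAG[["stripByteCounts"]], 4L, 1L, bytesPerPage)
    entry(TAG[["sampleFormat"]], 3L, 1L, 3L)
    u32(if (k < nPages) ifdStart + k * ifdSize else 0L)
  }
  invisible(path)
}

planesAreInteger16 <- function(planes) {
  for (p in planes)
    if (min(p) < 0 || max(p) > 65535 || any(p != round(p))) return(FALSE)
  TRUE
}

#' Write a SIM stack to a multi-page TIFF with a JSON sidecar
#'
#' Raw stacks with integer intensities within 16 bits are written as 16-bit
#' pages (via the `tiff` package); anything else — in particular full-range
#' reconstructed data with negative values — is written as uncompressed
#' 32-bit float pages. Plane order is CPZAT for raw stacks and CZT (channel
#' fastest) for reconstructed stacks. A sidecar `<path>.json` records the
#' dimension counts, ordering, bit depth and pixel sizes so the stack can be
#' read back without guessing.
#'
#' @param stack a [RawSIMStack] or [ReconStack]
#' @param path output TIFF path
#' @param sidecar write the JSON sidecar (default TRUE)
#' @return `path`, invisibly
#' @export
writeStackTIFF <- function(stack, path, sidecar = TRUE) {
  if (is(stack, "RawSIMStack")) {
    seq3 <- planeSequence(stack)
    planes <- lapply(seq_len(dim(seq3)[3L]), function(i) seq3[, , i])
    d <- dim(stack@data)
    meta <- list(kind = "raw", order = "CPZAT",
                 C = d[3], P = d[4], Z = d[5], A = d[6], T = d[7],
                 bit_depth = stack@bitDepth,
                 pixel_xy = stack@pixelXY, pixel_z = stack@pixelZ)
  } else if (is(stack, "ReconStack")) {
    d <- dim(stack@data)
    flat <- array(stack@data, c(d[1], d[2], prod(d[3:5])))
    planes <- lapply(seq_len(dim(flat)[3L]), function(i) flat[, , i])
    meta <- list(kind = "recon", order = "CZT",
                 C = d[3], Z = d[4], T = d[5],
                 full_range = stack@fullRange,
                 pixel_xy = stack@pixelXY, pixel_z = stack@pixelZ)
  } else stop("stack must be a RawSIMStack or ReconStack")
  if (is(stack, "RawSIMStack") && planesAreInteger16(planes)) {
    tiff::writeTIFF(lapply(planes, function(p) p / 65535),
                    path, bits.per.sample = 16L, compression = "none")
    meta$sample_format <- "uint16"
  } else {
    writeFloatTiff(planes, path)
    meta$sample_format <- "float32"
  }
  if (sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

readSidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::fromJSON(sc) else NULL
}

mergeStackConfig <- function(path, config) {
  side <- readSidecar(path)
  if (is.null(side)) side <- list()
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config)
  if (is.null(config)) config <- list()
  modifyList(side, config)
}

pixelOrDefault <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) return(as.numeric(cfg[[key]]))
  warning("no ", key, " metadata; defaulting to ", default, " um",
          call. = FALSE)
  default
}

#' Read a raw SIM stack from a multi-page TIFF
#'
#' Dimension counts and plane ordering are taken from the JSON sidecar
#' written by [writeStackTIFF()] when present, overridden/completed by
#' `config` (a named list or a path to a JSON file with entries `order`,
#' `C`, `P`, `Z`, `A`, `T`, `bit_depth`, `pixel_xy`, `pixel_z`). Planes in a
#' non-canonical order are reordered to CPZAT on the fly. Missing pixel
#' sizes fall back to 0.08/0.125 um with a warning.
#'
#' @param path TIFF file
#' @param config named list or JSON path supplying/overriding metadata
#' @return a [RawSIMStack]
#' @export
readRawStackTIFF <- function(path, config = NULL) {
  cfg <- mergeStackConfig(path, config)
  need <- c("C", "P", "Z", "A", "T")
  if (!all(need %in% names(cfg)))
    stop("dimension counts ", paste(setdiff(need, names(cfg)), collapse = ", "),
         " missing: supply a sidecar or config")
  dims <- vapply(cfg[need], as.integer, 1L)
  planes <- readTiffPlanes(path)
  if (length(planes) != prod(dims))
    stop("page count ", length(planes), " does not match C*P*Z*A*T = ",
         prod(dims))
  arr <- array(unlist(planes), c(dim(planes[[1L]]), length(planes)))
  reorderToCPZAT(arr, if (is.null(cfg$order)) "CPZAT" else cfg$order, dims,
                 bitDepth = if (is.null(cfg$bit_depth)) 16 else cfg$bit_depth,
                 pixelXY = pixelOrDefault(cfg, "pixel_xy", 0.08),
                 pixelZ = pixelOrDefault(cfg, "pixel_z", 0.125))
}

#' Read a reconstructed SIM stack from a multi-page TIFF
#'
#' @param path TIFF file (32-bit float or integer pages, uncompressed)
#' @param config named list or JSON path with `C`, `Z`, `T`, `full_range`,
#'   `pixel_xy`, `pixel_z`; sidecar values are used when present. A
#'   single-channel, single-timepoint stack needs no metadata.
#' @return a [ReconStack]
#' @export
readReconStackTIFF <- function(path, config = NULL) {
  cfg <- mergeStackConfig(path, config)
  planes <- readTiffPlanes(path)
  n <- length(planes)
  C <- if (is.null(cfg$C)) 1L else as.integer(cfg$C)
  T <- if (is.null(cfg$T)) 1L else as.integer(cfg$T)
  Z <- if (is.null(cfg$Z)) n %/% (C * T) else as.integer(cfg$Z)
  if (C * Z * T != n)
    stop("page count ", n, " does not match C*Z*T = ", C * Z * T)
  arr <- array(unlist(planes), c(dim(planes[[1L]]), C, Z, T))
  ReconStack(arr,
             pixelXY = pixelOrDefault(cfg, "pixel_xy", 0.04),
             pixelZ = pixelOrDefault(cfg, "pixel_z", 0.125),
             fullRange = !isFALSE(cfg$full_range))
}
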
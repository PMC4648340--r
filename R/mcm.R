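## Modulation Contrast Map: reconstructed intensity coloured by raw MCNR.

## 256-entry heat LUT spanning MCNR 0..ceiling: purple (low contrast)
## through red and orange to yellow (high contrast)
mcnrLUT <- function(n = 256L) {
  ramp <- colorRamp(c("#2D004B", "purple", "red", "orange", "yellow"))
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Modulation contrast map (MCM)
#'
#' Renders reconstructed data with the colour information of the raw-data
#' modulation contrast: each voxel's colour is a heat-LUT lookup of the
#' MCNR value (display ceiling 24), multiplied by the reconstructed
#' intensity normalized to the image maximum — so that apparent "features"
#' whose underlying raw stripe contrast is low reveal themselves in the
#' purple end. Voxels saturated in one or more raw angles/phases (at
#' `2^bitDepth - 1`) are coloured pure green to mark missing stripe
#' information. The MCNR map is registered to the reconstructed grid by
#' nearest-neighbour 2x upscaling (interpolation would smear the saturation
#' mask).
#'
#' @param recon a [ReconStack] (2x the raw lateral dimensions)
#' @param mcnrResult an [McnrResult] computed from the matching raw stack
#' @param raw the matching [RawSIMStack] (for the saturation mask)
#' @param channel,timepoint channel and timepoint to render
#' @param displayCeiling MCNR display ceiling for the LUT
#' @return an [McmImage]
#' @export
modulationContrastMap <- function(recon, mcnrResult, raw, channel = 1L,
                                  timepoint = 1L, displayCeiling = 24) {
  dR <- dim(recon@data); dM <- dim(mcnrResult@map)
  if (dR[1] != 2L * dM[1] || dR[2] != 2L * dM[2] || dR[4] != dM[3])
    stop("reconstruction is not 2x the lateral size of the MCNR map ",
         "(or z mismatch)")
  Y2 <- dR[1]; X2 <- dR[2]; Z <- dR[4]
  satLevel <- 2^raw@bitDepth - 1
  lut <- mcnrLUT()
  inten <- pmax(recon@data[, , channel, , timepoint], 0)
  if (length(dim(inten)) == 2L) dim(inten) <- c(dim(inten), 1L)
  mx <- max(inten)
  if (mx > 0) inten <- inten / mx
  rgb <- array(0, c(Y2, X2, 3L, Z))
  satMask <- array(FALSE, c(Y2, X2, Z))
  for (z in seq_len(Z)) {
    mapUp <- nnUpscale2x(mcnrResult@map[, , z, channel])
    idx <- pmin(pmax(ceiling(255 * clamp(mapUp / displayCeiling, 0, 1)), 0), 255) + 1L
    ## saturation in any raw phase/angle at this voxel
    sat <- apply(raw@data[, , channel, , z, , timepoint, drop = FALSE] >=
                   satLevel, c(1, 2), any)
    satUp <- nnUpscale2x(sat)
    satMask[, , z] <- satUp
    w <- inten[, , z]
    for (ch in 1:3) {
      col <- matrix(lut[idx, ch], Y2, X2) * w
      col[satUp] <- if (ch == 2L) w[satUp] else 0
      rgb[, , ch, z] <- col
    }
  }
  new("McmImage", rgb = rgb, saturationMask = satMask)
}

setMethod("show", "McmImage", function(object) {
  d <- dim(object@rgb)
  cat("Modulation contrast map:", d[2], "x", d[1], "px,", d[4],
      "slice(s);", sum(object@saturationMask), "saturated voxel(s)\n")
})
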
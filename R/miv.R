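## Motion & Illumination Variation: CMY false-colour merge of phase
## averages per angle.

#' Motion and illumination variation check (MIV)
#'
#' Averages the phase-shifted images of each illumination angle at each
#' z-plane, intensity-normalizes the three angle images (each scaled so its
#' mean equals the grand mean of the three at that z), assigns cyan,
#' magenta and yellow, and merges additively to RGB
#' (`R = (M+Y)/2, G = (C+Y)/2, B = (C+M)/2`). Features sampled evenly in
#' all angles render grey/white; motion between the temporally separated
#' angle acquisitions or uneven illumination appears as colour. Requires
#' exactly three angles.
#'
#' @param raw a [RawSIMStack] with `nAngles == 3`
#' @param channel,timepoint channel and timepoint to analyse
#' @return a [MivImage]
#' @export
motionIlluminationVariation <- function(raw, channel = 1L, timepoint = 1L) {
  d <- dim(raw@data)
  if (d[6] != 3L)
    stop("MIV assumes exactly 3 illumination angles; stack has ", d[6])
  Y <- d[1]; X <- d[2]; Z <- d[5]
  ang <- array(0, c(Y, X, 3L, Z))
  for (z in seq_len(Z)) {
    for (a in 1:3)
      ang[, , a, z] <- apply(raw@data[, , channel, , z, a, timepoint,
                                      drop = FALSE], c(1, 2), mean)
    grand <- mean(ang[, , , z])
    for (a in 1:3) {
      m <- mean(ang[, , a, z])
      if (m > 0) ang[, , a, z] <- ang[, , a, z] * (grand / m)
    }
  }
  cyan <- ang[, , 1, , drop = FALSE]
  magenta <- ang[, , 2, , drop = FALSE]
  yellow <- ang[, , 3, , drop = FALSE]
  rgb <- array(0, c(Y, X, 3L, Z))
  rgb[, , 1, ] <- (magenta + yellow) / 2
  rgb[, , 2, ] <- (cyan + yellow) / 2
  rgb[, , 3, ] <- (cyan + magenta) / 2
  for (ch in 1:3) rgb[, , ch, ] <- rescale01(rgb[, , ch, ])
  new("MivImage", angleImages = ang, rgb = rgb)
}

setMethod("show", "MivImage", function(object) {
  d <- dim(object@rgb)
  cat("MIV image:", d[2], "x", d[1], "px,", d[4], "z-slice(s);",
      "angles coloured C/M/Y, merged to RGB\n")
})
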
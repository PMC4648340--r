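## Illumination Pattern Focus: orthogonal view of the striped illumination
## per angle, for assessing axial alignment of the pattern with the focal
## plane.

## first-order peak of a DC-centred amplitude spectrum, excluding the
## central disc and the frequency axes; returns frequencies in cycles/px
detectStripePeak <- function(amp, discRadiusFrac = 1 / 16,
                             bandHalfWidth = 1L) {
  d <- dim(amp)
  mask <- centreAxisMask(d[1], d[2], discRadiusFrac, bandHalfWidth)
  amp[mask] <- -Inf
  if (!any(is.finite(amp))) stop("no detectable stripe peak")
  ij <- which(amp == max(amp), arr.ind = TRUE)[1L, ]
  cy <- floor(d[1] / 2) + 1L; cx <- floor(d[2] / 2) + 1L
  ky <- (ij[1L] - cy) / d[1]
  kx <- (ij[2L] - cx) / d[2]
  ## canonical half-plane: kx > 0, or kx == 0 and ky > 0
  if (kx < 0 || (kx == 0 && ky < 0)) { kx <- -kx; ky <- -ky
    ij <- c(2L * cy - ij[1L], 2L * cx - ij[2L]) }
  list(i = ij[1L], j = ij[2L], kx = kx, ky = ky,
       thetaDeg = atan2(ky, kx) * 180 / pi)
}

#' Illumination pattern focus calibration (IPF)
#'
#' Orthogonal (xz) view of the illumination stripe pattern for each angle,
#' from raw data of a dense, flat, high-contrast sample (a sub-resolution
#' bead lawn). Per angle: slice-to-slice intensity is normalized by a
#' simple ratio of mean slice intensities; the first phase of each z-plane
#' is taken; the stripe orientation is estimated from the dominant
#' first-order FFT peak of the central slice and the stack is rotated so
#' the stripes are vertical; the rotated sub-stack is resliced to an
#' xz-view by a maximum-intensity projection along the stripe direction.
#' A well-focused pattern shows a single bright layer at the focal plane;
#' an axially offset pattern modulation produces a staggered "zipper" of
#' bright segments alternating with stripe phase.
#'
#' @param raw a [RawSIMStack] of a dense calibration sample
#' @param channel,timepoint,phase channel/timepoint/phase to use
#' @return an [IpfMontage]
#' @export
illuminationPatternFocus <- function(raw, channel = 1L, timepoint = 1L,
                                     phase = 1L) {
  d <- dim(raw@data)
  Z <- d[5]; A <- d[6]
  panels <- vector("list", A)
  thetas <- numeric(A)
  factors <- vector("list", A)
  for (a in seq_len(A)) {
    sub <- raw@data[, , channel, phase, , a, timepoint]
    if (length(dim(sub)) == 2L) dim(sub) <- c(dim(sub), 1L)
    norm <- normalizeSliceMeans(sub)
    sub <- norm$data
    factors[[a]] <- norm$factors
    zMid <- floor(Z / 2) + 1L
    peak <- detectStripePeak(fftshift2(Mod(fft2(sub[, , zMid]))))
    thetas[a] <- peak$thetaDeg
    panel <- matrix(0, Z, d[2])
    for (z in seq_len(Z)) {
      rot <- EBImage::imageData(EBImage::rotate(
        EBImage::Image(sub[, , z]), peak$thetaDeg,
        output.dim = c(d[1], d[2]), bg.col = 0))
      ## stripes now vertical: project along y (the stripe direction)
      panel[z, ] <- apply(rot, 2L, max)
    }
    panels[[a]] <- panel
  }
  gap <- matrix(NA_real_, 1L, d[2])
  montage <- do.call(rbind, lapply(seq_len(A), function(a)
    if (a < A) rbind(panels[[a]], gap) else panels[[a]]))
  new("IpfMontage", panels = panels, montage = montage, thetaDeg = thetas,
      normFactors = factors)
}

setMethod("show", "IpfMontage", function(object) {
  cat("Illumination pattern focus montage:", length(object@panels),
      "angle panel(s),", nrow(object@panels[[1]]), "z x",
      ncol(object@panels[[1]]), "px\n")
  cat("  estimated stripe orientations (deg):",
      paste(sprintf("%.1f", object@thetaDeg), collapse = ", "), "\n")
})
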
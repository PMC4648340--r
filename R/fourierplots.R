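## Reconstructed Fourier plots: lateral spectra (FTL), axial spectrum of
## the resliced central section (FTO), radial profile (FTR).

#' Reconstructed Fourier plots (FTL / FTO / FTR)
#'
#' Frequency-space view of reconstructed data for resolution assessment.
#' Per z-slice a 2-D FFT of the (optionally pre-processed) data gives an
#' amplitude spectrum displayed with gamma correction (`amplitude^0.2`, the
#' default) or as a `log(amplitude^2)` power spectrum with mode-max
#' rescaling. Pre-processing by default subtracts the lower half of the
#' background intensities — everything below the stack mode — and clips at
#' zero ("auto cutoff"), suppressing the frequency contribution of
#' reconstructed noise; a manual cutoff or no cutoff can be chosen instead,
#' and a Gaussian edge window (6% width) can be applied to remove
#' horizontal/vertical edge-artifact stripes. Outputs:
#'
#' * `ftl` — DC-centred amplitude spectra per z-slice, with concentric
#'   rings annotating spatial resolutions (ring radius in frequency pixels
#'   is `X * pixelXY / d` for resolution `d` in micrometres);
#' * `fto` — the axial spectrum of the central xz-section after
#'   interpolating z to isotropic voxels (factor `pixelZ / pixelXY`);
#' * `ftr` — the radially averaged amplitude profile of the central slice,
#'   whose inflection point approximates the effective frequency support.
#'
#' @param recon a [ReconStack]
#' @param channel,timepoint channel and timepoint to analyse
#' @param cutoff `"auto"` (stack mode), a numeric value, or NULL for none
#' @param window apply the Gaussian edge window before transforming
#' @param windowPct window width, percent of image width
#' @param scaling `"gamma"` (amplitude^gamma) or `"log"` (log power,
#'   mode-max rescaled per slice)
#' @param gamma gamma exponent for the default scaling
#' @param ringResolutions resolutions to annotate, micrometres
#' @param displayRange display scaling bounds for the gamma mode
#' @return a [FourierPlotSet]
#' @export
fourierPlots <- function(recon, channel = 1L, timepoint = 1L,
                         cutoff = "auto", window = FALSE, windowPct = 6,
                         scaling = c("gamma", "log"), gamma = 0.2,
                         ringResolutions = c(0.2, 0.13, 0.1),
                         displayRange = c(2, 40)) {
  scaling <- match.arg(scaling)
  v <- recon@data[, , channel, , timepoint]
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  d <- dim(v)
  Y <- d[1]; X <- d[2]; Z <- d[3]
  cutValue <- if (is.null(cutoff)) NULL
    else if (identical(cutoff, "auto")) stackMode(v) else as.numeric(cutoff)
  if (!is.null(cutValue)) v <- pmax(v - cutValue, 0)
  win <- if (window) gaussianEdgeWindow(Y, X, windowPct) else NULL
  scaleSpec <- function(amp) {
    if (scaling == "gamma") amp^gamma
    else {
      lp <- log(amp^2 + 1e-30)
      m <- stackMode(lp)
      r <- max(lp) - m
      if (r <= 0) lp * 0 else clamp((lp - m) / r, 0, 1)
    }
  }
  ftl <- array(0, c(Y, X, Z))
  for (z in seq_len(Z)) {
    sl <- v[, , z]
    if (!is.null(win)) sl <- sl * win
    ftl[, , z] <- scaleSpec(fftshift2(Mod(fft2(sl))))
  }
  zMid <- floor(Z / 2) + 1L
  ## radial profile of the central slice
  prof <- radialProfile(ftl[, , zMid])
  radius <- seq_along(prof) - 1L
  fieldUm <- X * recon@pixelXY
  ftr <- data.frame(radiusPx = radius,
                    freqPerUm = radius / fieldUm,
                    resolutionUm = ifelse(radius > 0, fieldUm / radius, Inf),
                    amplitude = prof)
  rings <- data.frame(resolutionUm = ringResolutions,
                      radiusPx = fieldUm / ringResolutions)
  ## axial spectrum: central xz reslice, z interpolated to isotropic voxels
  resliceFactor <- recon@pixelZ / recon@pixelXY
  yMid <- floor(Y / 2) + 1L
  if (Z >= 2L) {
    xz <- t(v[yMid, , ])                        # (Z, X)
    nz2 <- max(2L, round(Z * resliceFactor))
    iso <- apply(xz, 2L, function(col)
      approx(seq_len(Z), col, xout = seq(1, Z, length.out = nz2))$y)
    if (window)
      iso <- iso * gaussianEdgeWindow(nrow(iso), ncol(iso), windowPct)
    fto <- scaleSpec(fftshift2(Mod(fft2(iso))))
  } else fto <- matrix(numeric(0), 0L, 0L)      # no axial view for one slice
  new("FourierPlotSet", ftl = ftl, fto = fto, ftr = ftr, rings = rings,
      options = list(cutoff = cutValue, window = window,
                     windowPct = windowPct, scaling = scaling,
                     gamma = gamma, displayRange = displayRange,
                     resliceFactor = resliceFactor, centralZ = zMid))
}

setMethod("show", "FourierPlotSet", function(object) {
  d <- dim(object@ftl)
  cat("Fourier plot set:", d[2], "x", d[1], "px,", d[3], "slice(s);",
      "scaling", object@options$scaling, "\n")
  cat("  cutoff:", if (is.null(object@options$cutoff)) "none"
      else signif(object@options$cutoff, 4),
      "| window:", object@options$window,
      "| reslice factor:", signif(object@options$resliceFactor, 4), "\n")
  cat("  rings (um -> px):",
      paste(sprintf("%.2f->%.1f", object@rings$resolutionUm,
                    object@rings$radiusPx), collapse = ", "), "\n")
})

#' Plot the radial Fourier profile (FTR)
#'
#' Radially averaged spectral amplitude against spatial frequency, with the
#' annotated resolution rings marked; the profile's inflection point
#' approximates the effective resolution of the reconstruction.
#'
#' @param fps a [FourierPlotSet]
#' @return invisibly NULL
#' @export
plotFtr <- function(fps) {
  ok <- is.finite(fps@ftr$amplitude)
  plot(fps@ftr$freqPerUm[ok], fps@ftr$amplitude[ok], type = "l",
       xlab = "spatial frequency (cycles/um)", ylab = "amplitude (scaled)",
       main = "Radial Fourier profile")
  abline(v = 1 / fps@rings$resolutionUm, col = "grey60", lty = 3)
  mtext(paste(fps@rings$resolutionUm, "um", collapse = "  "), side = 3,
        cex = 0.8)
  invisible(NULL)
}
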
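## Spherical Aberration Mismatch: z-profile of slice minima vs feature
## intensity.

#' Spherical aberration mismatch check (SAM)
#'
#' Plots the minimum intensity of each z-section against the mean intensity
#' of Otsu-selected features, and reports the z-minimum variation
#' `ZMV = sd(slice minima) / mean(feature intensity)` — a unitless measure
#' of the depth of the axial intensity dips that appear when the sample's
#' point-spread conditions do not match the OTF used for reconstruction
#' (spherical aberration, refractive-index mismatch, or a shifted
#' illumination pattern focus). Most useful as a relative measure between
#' similar samples; works best with flat high-contrast samples such as bead
#' layers. Requires full-range (untrimmed) data.
#'
#' @param recon a [ReconStack] with at least 3 z-slices
#' @param channel,timepoint channel and timepoint to analyse
#' @return a [SamStats]
#' @export
sphericalAberrationMismatch <- function(recon, channel = 1L,
                                        timepoint = 1L) {
  if (!recon@fullRange)
    warning("reconstructed data flagged as range-clipped: slice minima of ",
            "trimmed data do not reflect reconstruction dips")
  Z <- dim(recon@data)[4L]
  if (Z < 3L) stop("SAM requires at least 3 z-slices")
  v <- recon@data[, , channel, , timepoint]
  cut <- otsuThreshold(v)
  fg <- v > cut
  if (!any(fg)) stop("Otsu foreground is empty; no features to normalize by")
  minima <- apply(v, 3L, min)
  featureMeans <- vapply(seq_len(Z), function(z) {
    sel <- fg[, , z]
    if (any(sel)) mean(v[, , z][sel]) else NA_real_
  }, 0)
  featureMean <- mean(v[fg])
  new("SamStats", minima = minima, featureMeans = featureMeans,
      featureMean = featureMean, zmv = sd(minima) / featureMean)
}

setMethod("show", "SamStats", function(object) {
  cat("Spherical aberration mismatch\n")
  cat(sprintf("  slice minima sd %.4g | feature mean %.4g | ZMV = %.4g\n",
              sd(object@minima), object@featureMean, object@zmv))
})

#' Plot slice minima and feature means against z
#'
#' @param stats a [SamStats]
#' @return invisibly NULL
#' @export
plotSam <- function(stats) {
  z <- seq_along(stats@minima)
  plot(z, stats@featureMeans, type = "b", col = "darkgreen", ylim =
         range(c(stats@minima, stats@featureMeans), na.rm = TRUE),
       xlab = "z-slice", ylab = "intensity",
       main = "Spherical aberration mismatch")
  lines(z, stats@minima, type = "b", col = "red")
  legend("right", bty = "n", col = c("darkgreen", "red"), lty = 1,
         legend = c("feature mean", "slice minimum"))
  mtext(sprintf("ZMV = %.4g", stats@zmv), side = 3)
  invisible(NULL)
}
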
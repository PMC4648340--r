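## Illumination Phase Steps: recover the illumination phase at the
## first-order spectral peak and report phase-stepping accuracy.

#' Illumination phase step calibration (IPS)
#'
#' Measures the actual phase of the illumination pattern in every raw
#' phase image and reports on phase-stepping reproducibility. Raw slices
#' are Fourier-transformed; the high-intensity region around the origin
#' (disc of radius 1/16 of the width) and bands along both frequency axes
#' are masked; the first-order spot is detected per angle as the strongest
#' remaining peak (summed over phases at the best-focus slice) and the
#' phase of the complex spectrum at that spot is read for every phase step
#' within the z-range. The per-z phase series are unwrapped and summarized
#' by the mean phase step, the standard deviation of successive steps
#' (step accuracy) and the standard deviation of the residuals around the
#' ideal staircase (offset stability). The nominal step is `2*pi/P`; the
#' sign of the recovered step follows the detected peak's half-plane, so
#' compare magnitudes.
#'
#' @param raw a [RawSIMStack] of a dense calibration sample
#' @param zRange analyse `zBest +/- zRange` slices, where `zBest` is the
#'   slice of maximum mean intensity (plane of best focus)
#' @param channel,timepoint channel and timepoint to analyse
#' @param discRadiusFrac,bandHalfWidth mask geometry (fractions of width /
#'   pixels)
#' @return an [IpsResult]
#' @export
illuminationPhaseSteps <- function(raw, zRange = 1L, channel = 1L,
                                   timepoint = 1L, discRadiusFrac = 1 / 16,
                                   bandHalfWidth = 1L) {
  d <- dim(raw@data)
  P <- d[4]; Z <- d[5]; A <- d[6]
  zMeans <- vapply(seq_len(Z), function(z)
    mean(raw@data[, , channel, , z, , timepoint]), 0)
  zBest <- which.max(zMeans)
  zs <- max(1L, zBest - zRange):min(Z, zBest + zRange)
  peaks <- matrix(0, A, 2L, dimnames = list(NULL, c("kx", "ky")))
  series <- vector("list", A)
  meanStep <- stepSD <- offsetSD <- numeric(A)
  for (a in seq_len(A)) {
    ampSum <- 0
    for (p in seq_len(P))
      ampSum <- ampSum + fftshift2(Mod(fft2(
        raw@data[, , channel, p, zBest, a, timepoint])))
    peak <- detectStripePeak(ampSum, discRadiusFrac, bandHalfWidth)
    peaks[a, ] <- c(peak$kx, peak$ky)
    phases <- matrix(0, P, length(zs))
    for (zi in seq_along(zs)) {
      raws <- numeric(P)
      for (p in seq_len(P)) {
        Fp <- fftshift2(fft2(raw@data[, , channel, p, zs[zi], a, timepoint]))
        raws[p] <- Arg(Fp[peak$i, peak$j])
      }
      phases[, zi] <- signal::unwrap(raws)
    }
    series[[a]] <- phases
    diffs <- as.vector(apply(phases, 2L, diff))
    meanStep[a] <- mean(diffs)
    stepSD[a] <- if (length(diffs) > 1L) sd(diffs) else 0
    resid <- sweep(phases, 1L, (seq_len(P) - 1L) * meanStep[a])
    offsetSD[a] <- if (length(resid) > 1L) sd(as.vector(resid)) else 0
  }
  new("IpsResult", peaks = peaks, phaseSeries = series,
      meanStep = meanStep, stepSD = stepSD, offsetSD = offsetSD,
      zUsed = as.integer(zs))
}

setMethod("show", "IpsResult", function(object) {
  A <- length(object@meanStep)
  cat("Illumination phase steps (z-slices ",
      paste(range(object@zUsed), collapse = "-"), ")\n", sep = "")
  for (a in seq_len(A))
    cat(sprintf(
      "  angle %d: peak (%.3f, %.3f) cyc/px | step %.4f rad | step sd %.2g | offset sd %.2g\n",
      a, object@peaks[a, 1], object@peaks[a, 2], object@meanStep[a],
      object@stepSD[a], object@offsetSD[a]))
})

#' Plot unwrapped phase series per angle
#'
#' @param ips an [IpsResult]
#' @return invisibly NULL
#' @export
plotIps <- function(ips) {
  A <- length(ips@phaseSeries)
  cols <- c("red", "green3", "blue", "black")[seq_len(min(A, 4))]
  allPh <- unlist(ips@phaseSeries)
  plot(NA, xlim = c(1, nrow(ips@phaseSeries[[1]])), ylim = range(allPh),
       xlab = "phase step", ylab = "unwrapped phase (rad)",
       main = "Illumination phase steps")
  for (a in seq_len(A))
    for (zi in seq_len(ncol(ips@phaseSeries[[a]])))
      lines(ips@phaseSeries[[a]][, zi], col = cols[(a - 1) %% 4 + 1])
  invisible(NULL)
}
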
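## Reconstructed Intensity Histogram: mode, extreme tails, min-to-max ratio.

#' Reconstructed intensity histogram check (RIH)
#'
#' Summarizes the full-range intensity distribution of reconstructed data.
#' The modal intensity (background) is the centre of the tallest bin of a
#' 256-bin stack histogram. Min* and Max* are the means of the extreme
#' tails — by default the lowest and highest 0.05% of voxels, subject to a
#' minimum of 100 — and the min-to-max ratio is
#' `MMR = (Max* - Mode) / |Min* - Mode|`. Reconstructed noise and ringing
#' produce the negative tail; an MMR near 1 means "features" are no larger
#' than the reconstruction artifacts. The tail voxel counts are reported so
#' that truncation zeros or saturated pixels skewing the tails can be
#' spotted. Requires untrimmed data covering the full intensity range
#' (a warning is issued otherwise).
#'
#' @param recon a [ReconStack]
#' @param channel,timepoint channel and timepoint to analyse
#' @param tailFraction tail size as a fraction of the voxel count
#' @param minTailPixels lower bound on the tail size
#' @return a [RihStats]
#' @export
reconstructedIntensityHistogram <- function(recon, channel = 1L,
                                            timepoint = 1L,
                                            tailFraction = 0.0005,
                                            minTailPixels = 100L) {
  if (!recon@fullRange)
    warning("reconstructed data flagged as range-clipped: the intensity ",
            "histogram is only meaningful for untrimmed full-range data ",
            "(\"discard negatives\" and equivalents must be deactivated)")
  v <- as.vector(recon@data[, , channel, , timepoint])
  n <- length(v)
  h <- stackHistogram(v)
  k <- which.max(h$counts)
  mode <- (h$breaks[k] + h$breaks[k + 1L]) / 2
  nTail <- min(n, max(floor(tailFraction * n), minTailPixels))
  vs <- sort(v)
  minStar <- mean(vs[seq_len(nTail)])
  maxStar <- mean(vs[(n - nTail + 1L):n])
  denom <- abs(minStar - mode)
  mmr <- if (denom < .Machine$double.eps * max(1, abs(mode))) {
    warning("|Min* - Mode| is zero: clipped-data signature, MMR undefined")
    NA_real_
  } else (maxStar - mode) / denom
  new("RihStats", mode = mode, minStar = minStar, maxStar = maxStar,
      nMin = as.integer(nTail), nMax = as.integer(nTail), mmr = mmr,
      breaks = h$breaks, counts = as.integer(h$counts))
}

setMethod("show", "RihStats", function(object) {
  cat("Reconstructed intensity histogram\n")
  cat(sprintf("  mode %.4g | Min* %.4g (n=%d) | Max* %.4g (n=%d)\n",
              object@mode, object@minStar, object@nMin, object@maxStar,
              object@nMax))
  cat(sprintf("  min-to-max ratio (MMR): %.3f\n", object@mmr))
})

#' Plot a reconstructed intensity histogram
#'
#' Linear (black) and log-scaled (grey) counts against intensity, with the
#' mode and the Min*/Max* tail means marked.
#'
#' @param stats a [RihStats]
#' @return invisibly NULL
#' @export
plotRih <- function(stats) {
  mids <- (head(stats@breaks, -1) + tail(stats@breaks, -1)) / 2
  counts <- stats@counts
  plot(mids, counts / max(counts), type = "h", col = "black",
       xlab = "intensity", ylab = "relative count (linear / log)",
       main = "Reconstructed intensity histogram")
  lines(mids, log1p(counts) / max(log1p(counts)), col = "grey50")
  abline(v = c(stats@mode, stats@minStar, stats@maxStar),
         col = c("blue", "red", "red"), lty = 2)
  mtext(sprintf("MMR = %.2f", stats@mmr), side = 3)
  invisible(NULL)
}
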
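## Channel Intensity Profile: per-plane intensity statistics of raw data.

#' Channel intensity profile (CIP)
#'
#' Computes per-plane mean intensities of a raw SIM stack (in phase, z,
#' angle, time order per channel) and summary statistics that identify the
#' type of intensity fluctuation present:
#'
#' * **TIV** — total intensity variation: the min-max range of plane means
#'   as a percentage of the maximum, over all phases and angles within a
#'   9-z window about the central slice (the reconstruction consumes
#'   adjacent z-sections, so fluctuations inside this window matter most).
#' * **decay** — estimated photobleaching: per angle, a least-squares fit
#'   of log mean intensity against within-angle acquisition index,
#'   reported as the percentage lost from first to last plane and averaged
#'   over angles.
#' * **maximum angle difference** — largest difference between per-angle
#'   window means, as a percentage of the brightest angle.
#' * **flicker** — mean over (angle, phase) series of the min-max range of
#'   that series' means across the 9-z window, as a percentage.
#'
#' For stacks with fewer than 9 z-slices the window is truncated to the
#' full stack and a note is emitted.
#'
#' @param raw a [RawSIMStack]
#' @param windowHalfWidth z half-width of the central window (default 4)
#' @return a [CipStats]
#' @export
channelIntensityProfile <- function(raw, windowHalfWidth = 4L) {
  d <- dim(raw@data)
  C <- d[3]; P <- d[4]; Z <- d[5]; A <- d[6]; TT <- d[7]
  ## plane means, indexed [p, z, a, t, c]
  mu <- apply(raw@data, 3:7, mean)              # dims (C, P, Z, A, T)
  mu <- aperm(mu, c(2, 3, 4, 5, 1))
  zc <- as.integer(ceiling(Z / 2))
  zWin <- max(1L, zc - windowHalfWidth):min(Z, zc + windowHalfWidth)
  if (length(zWin) < 2L * windowHalfWidth + 1L)
    message("CIP: stack has ", Z, " z-slices; intensity-variation window ",
            "truncated to the full stack")
  planeMeans <- matrix(aperm(mu, c(1, 2, 3, 4, 5)), ncol = C)
  tiv <- numeric(C); meanDecay <- numeric(C)
  maxAngleDiff <- numeric(C); flicker <- numeric(C)
  decayPerAngle <- matrix(0, A, C)
  for (c in seq_len(C)) {
    win <- mu[, zWin, , , c, drop = FALSE]
    tiv[c] <- 100 * (max(win) - min(win)) / max(win)
    for (a in seq_len(A)) {
      series <- as.vector(mu[, , a, , c])       # (p fastest, z, t) order
      n <- length(series)
      if (all(series > 0) && n > 1L) {
        slope <- coef(lm(log(series) ~ seq_len(n)))[2L]
        decayPerAngle[a, c] <- 100 * (1 - exp(slope * (n - 1)))
      }
    }
    meanDecay[c] <- mean(decayPerAngle[, c])
    angleMeans <- apply(mu[, zWin, , , c, drop = FALSE], 3, mean)
    maxAngleDiff[c] <- 100 * (max(angleMeans) - min(angleMeans)) /
      max(angleMeans)
    fl <- numeric(0)
    for (a in seq_len(A)) for (p in seq_len(P)) for (t in seq_len(TT)) {
      s <- mu[p, zWin, a, t, c]
      fl <- c(fl, 100 * (max(s) - min(s)) / max(s))
    }
    flicker[c] <- mean(fl)
  }
  new("CipStats", planeMeans = planeMeans, tiv = tiv,
      decayPerAngle = decayPerAngle, meanDecay = meanDecay,
      maxAngleDiff = maxAngleDiff, flicker = flicker,
      windowZ = range(zWin), nWindowPlanes = length(zWin) * P * A * TT)
}

setMethod("show", "CipStats", function(object) {
  C <- ncol(object@planeMeans)
  cat("Channel intensity profile (", nrow(object@planeMeans),
      " planes/channel, window z ", object@windowZ[1], "-",
      object@windowZ[2], ", ", object@nWindowPlanes, " images)\n", sep = "")
  for (c in seq_len(C))
    cat(sprintf(
      "  ch%d: TIV %.1f%% | decay %.1f%% | angle diff %.1f%% | flicker %.1f%%\n",
      c, object@tiv[c], object@meanDecay[c], object@maxAngleDiff[c],
      object@flicker[c]))
})

#' Plot a channel intensity profile
#'
#' Per-plane mean intensity against CPZAT plane index, channels coloured
#' red/green/blue then black, with the central 9-z window's angle blocks
#' implicit in the plane ordering.
#'
#' @param stats a [CipStats]
#' @param relative plot means relative to each channel's first plane
#' @return invisibly, the matrix of plotted values
#' @export
plotCip <- function(stats, relative = FALSE) {
  pm <- stats@planeMeans
  if (relative) pm <- sweep(pm, 2, pm[1, ], "/")
  cols <- c("red", "green3", "blue",
            rep("black", max(0, ncol(pm) - 3)))[seq_len(ncol(pm))]
  plot(NA, xlim = c(1, nrow(pm)), ylim = range(pm),
       xlab = "plane (phase, z, angle, time order)",
       ylab = if (relative) "relative mean intensity" else "mean intensity",
       main = "Channel intensity profile")
  for (c in seq_len(ncol(pm))) lines(pm[, c], col = cols[c])
  legend("bottomleft", bty = "n", col = cols, lty = 1,
         legend = paste0("ch", seq_len(ncol(pm))))
  invisible(pm)
}
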
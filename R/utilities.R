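## Image processing utilities: pseudo-widefield, threshold & 16-bit
## conversion, stack FFT.

#' Raw SI to pseudo-widefield (PWF)
#'
#' Averages all phases and angles of each raw z-slice — over P equally
#' spaced phase steps the stripe modulation cancels exactly, leaving the
#' equivalent conventional widefield image — and rescales laterally by a
#' factor of two with bicubic (Catmull-Rom) interpolation so the pixel
#' grid matches reconstructed data. Optional "simple ratio" normalization
#' pre-scales every raw plane to the channel's grand mean, correcting
#' bleaching and flicker. Negative interpolation undershoot is clipped at
#' zero.
#'
#' @param raw a [RawSIMStack]
#' @param normalize apply simple-ratio intensity normalization first
#' @return a [ReconStack]-shaped object on the doubled grid (values >= 0,
#'   `pixelXY` halved)
#' @export
pseudoWidefield <- function(raw, normalize = FALSE) {
  d <- dim(raw@data)
  Y <- d[1]; X <- d[2]; C <- d[3]; P <- d[4]; Z <- d[5]; A <- d[6]
  TT <- d[7]
  out <- array(0, c(2L * Y, 2L * X, C, Z, TT))
  for (c in seq_len(C)) {
    dat <- raw@data[, , c, , , , , drop = FALSE]
    dim(dat) <- c(Y, X, P, Z, A, TT)
    if (normalize) {
      flat <- array(dat, c(Y, X, P * Z * A * TT))
      dat <- array(normalizeSliceMeans(flat)$data, dim(dat))
    }
    for (t in seq_len(TT)) for (z in seq_len(Z)) {
      wf <- matrix(0, Y, X)
      for (a in seq_len(A)) for (p in seq_len(P))
        wf <- wf + dat[, , p, z, a, t]
      wf <- wf / (P * A)
      out[, , c, z, t] <- pmax(bicubicUpscale2x(wf), 0)
    }
  }
  ReconStack(out, pixelXY = raw@pixelXY / 2, pixelZ = raw@pixelZ,
             fullRange = TRUE)
}

#' Threshold and 16-bit conversion (THR)
#'
#' Discards intensities below a threshold — by default the stack's modal
#' intensity, the peak of the full-range histogram, below which lies no
#' feature information — and linearly fills the 16-bit range with the
#' remainder: the threshold maps to 0 and the channel maximum to 65535.
#' Channels are converted independently.
#'
#' @param recon a [ReconStack] (full-range for the automatic mode)
#' @param threshold `"auto"` (per-channel stack mode) or numeric threshold
#'   value(s), recycled across channels
#' @return integer array with the dimensions of `stackData(recon)`;
#'   per-channel thresholds are attached as attribute `"thresholds"`
#' @export
threshold16bit <- function(recon, threshold = "auto") {
  d <- dim(recon@data)
  C <- d[3]
  if (identical(threshold, "auto") && !recon@fullRange)
    warning("automatic mode-thresholding of range-clipped data: the ",
            "histogram mode may not reflect the background")
  out <- array(0L, d)
  thr <- numeric(C)
  for (c in seq_len(C)) {
    v <- recon@data[, , c, , , drop = FALSE]
    thr[c] <- if (identical(threshold, "auto")) stackMode(v)
      else as.numeric(threshold)[(c - 1L) %% length(threshold) + 1L]
    mx <- max(v)
    if (mx <= thr[c])
      stop("channel ", c, ": threshold ", signif(thr[c], 4),
           " leaves no intensity range (max ", signif(mx, 4), ")")
    out[, , c, , ] <- as.integer(round(
      65535 * pmax(v - thr[c], 0) / (mx - thr[c])))
  }
  attr(out, "thresholds") <- thr
  out
}

#' Stack FFT utility
#'
#' 2-D Fourier transform of every slice of a stack: a Gaussian edge window
#' (default 6% of the image width) suppresses edge discontinuities, the
#' slice is zero-padded to the next power-of-two square, transformed, and
#' the amplitude spectrum returned DC-centred with the chosen scaling:
#' `"log"` (log-scaled power, the default), `"gamma"` (`amplitude^gamma`),
#' or `"none"` (raw amplitude, useful for quantitative work).
#'
#' @param stack a [RawSIMStack], [ReconStack], 3-D array `(y, x, n)` or a
#'   single matrix
#' @param windowPct Gaussian window width, percent of width (0 to 50;
#'   0 disables)
#' @param scaling `"log"`, `"gamma"` or `"none"`
#' @param gamma exponent for `"gamma"` scaling
#' @return 3-D array `(k, k, n)` of scaled spectra (k = padded size), with
#'   attributes `"scaling"`, `"windowPct"`, `"padSize"`
#' @export
stackFFT <- function(stack, windowPct = 6, scaling = c("log", "gamma", "none"),
                     gamma = 0.2) {
  scaling <- match.arg(scaling)
  if (windowPct < 0 || windowPct > 50)
    stop("windowPct must be in [0, 50]")
  planes <- if (is(stack, "RawSIMStack")) planeSequence(stack)
    else if (is(stack, "ReconStack")) {
      d <- dim(stack@data)
      array(stack@data, c(d[1], d[2], prod(d[3:5])))
    } else if (is.matrix(stack)) array(stack, c(dim(stack), 1L))
    else stack
  d <- dim(planes)
  n <- nextPow2(max(d[1], d[2]))
  win <- if (windowPct > 0) gaussianEdgeWindow(d[1], d[2], windowPct)
    else NULL
  out <- array(0, c(n, n, d[3]))
  for (k in seq_len(d[3])) {
    sl <- planes[, , k]
    if (!is.null(win)) sl <- sl * win
    padded <- matrix(0, n, n)
    padded[seq_len(d[1]), seq_len(d[2])] <- sl
    amp <- fftshift2(Mod(fft2(padded)))
    out[, , k] <- switch(scaling,
                         log = log(amp^2 + 1e-30),
                         gamma = amp^gamma,
                         none = amp)
  }
  structure(out, scaling = scaling, windowPct = windowPct, padSize = n)
}
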
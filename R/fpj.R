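## Raw Fourier Projection: frequency-space view of the whole raw stack.

#' Raw Fourier projection (FPJ)
#'
#' For each raw plane: apply a Gaussian edge window (6% of the image
#' width), 2-D FFT, and log-power scaling `log(amplitude^2)`; then take a
#' maximum-intensity projection over all phases, z-sections and angles per
#' channel. The central circular region (diameter 1/8 of the image width)
#' is filled with the minimum value before min-max rescaling, so that the
#' first- and second-order illumination spots — one pair per angle — stand
#' out. Non-square planes are zero-padded to square before transforming.
#'
#' @param raw a [RawSIMStack]
#' @param windowPct Gaussian window width, percent of image width
#' @param timepoint timepoint to analyse
#' @return 3-D array `(y, x, channel)`: rescaled projections (DC centred);
#'   the unfilled, unrescaled projection is attached as attribute
#'   `"prefill"`
#' @export
rawFourierProjection <- function(raw, windowPct = 6, timepoint = 1L) {
  d <- dim(raw@data)
  C <- d[3]; P <- d[4]; Z <- d[5]; A <- d[6]
  n <- max(d[1], d[2])
  win <- gaussianEdgeWindow(d[1], d[2], windowPct)
  out <- array(0, c(n, n, C))
  pre <- array(-Inf, c(n, n, C))
  for (c in seq_len(C)) {
    proj <- matrix(-Inf, n, n)
    for (a in seq_len(A)) for (z in seq_len(Z)) for (p in seq_len(P)) {
      plane <- raw@data[, , c, p, z, a, timepoint] * win
      if (d[1] != n || d[2] != n) {
        padded <- matrix(0, n, n)
        padded[seq_len(d[1]), seq_len(d[2])] <- plane
        plane <- padded
      }
      amp2 <- Mod(fft2(plane))^2
      proj <- pmax(proj, log(amp2 + 1e-30))
    }
    proj <- fftshift2(proj)
    pre[, , c] <- proj
    cx <- floor(n / 2) + 1
    disc <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+") <= (n / 16)^2
    proj[disc] <- min(proj)
    out[, , c] <- rescale01(proj)
  }
  attr(out, "prefill") <- pre
  out
}
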
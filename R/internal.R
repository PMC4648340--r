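## Shared numeric helpers: histograms, Otsu wrapper, FFT utilities,
## windowing, interpolation.

## modal intensity of float data: 256-bin histogram over [min, max],
## mode = centre of the tallest bin (ties -> lowest bin)
stackMode <- function(v, nBins = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nBins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nBins)
  k <- which.max(counts)
  (breaks[k] + breaks[k + 1L]) / 2
}

stackHistogram <- function(v, nBins = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  breaks <- seq(r[1], r[2], length.out = nBins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(breaks = breaks, counts = tabulate(idx, nbins = nBins))
}

## Otsu threshold on arbitrary-scale data via EBImage (256-level histogram
## over the data range); values strictly above the threshold are foreground
otsuThreshold <- function(x) {
  v <- x[is.finite(x)]
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  img <- EBImage::Image(matrix((v - r[1]) / (r[2] - r[1]), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  r[1] + thr * (r[2] - r[1])
}

## centre the DC component of a 2-D spectrum at (floor(n/2)+1, floor(m/2)+1)
fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- floor(d[1] / 2); s2 <- floor(d[2] / 2)
  m[c((s1 + 1):d[1], seq_len(s1)), c((s2 + 1):d[2], seq_len(s2))]
}

fft2 <- function(m) fft(m)

## separable Gaussian edge taper: each border of width pct% of the
## dimension is attenuated by a half-Gaussian (sigma = border/3, so the
## outermost pixel is ~0.011); the interior is untouched
gaussianEdgeWindow <- function(ny, nx, pct = 6) {
  taper <- function(n) {
    b <- pct / 100 * n
    if (b < 1) return(rep(1, n))
    d <- pmin(seq_len(n) - 1, n - seq_len(n))   # distance from nearest edge
    ifelse(d >= b, 1, exp(-0.5 * ((b - d) / (b / 3))^2))
  }
  outer(taper(ny), taper(nx))
}

nextPow2 <- function(n) 2^ceiling(log2(n))

## mean amplitude in integer-radius annuli about the DC-centred origin
radialProfile <- function(m) {
  d <- dim(m)
  cy <- floor(d[1] / 2) + 1; cx <- floor(d[2] / 2) + 1
  r <- sqrt(outer((seq_len(d[1]) - cy)^2, (seq_len(d[2]) - cx)^2, "+"))
  rb <- floor(r)
  nb <- floor(min(d) / 2)
  keep <- rb < nb
  means <- tapply(m[keep], rb[keep], mean)
  out <- rep(NA_real_, nb)
  out[as.integer(names(means)) + 1L] <- means
  out
}

## mask for first-order peak detection in a DC-centred amplitude spectrum:
## disc of radius n/16 about the origin plus bands of half-width bw along
## both frequency axes (DC leakage and edge artifacts live there)
centreAxisMask <- function(ny, nx, discRadiusFrac = 1 / 16, bandHalfWidth = 1L) {
  cy <- floor(ny / 2) + 1; cx <- floor(nx / 2) + 1
  r2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
  mask <- r2 <= (min(ny, nx) * discRadiusFrac)^2
  mask[abs(seq_len(ny) - cy) <= bandHalfWidth, ] <- TRUE
  mask[, abs(seq_len(nx) - cx) <= bandHalfWidth] <- TRUE
  mask
}

## Catmull-Rom (a = -0.5) separable 2x upsampling; weights sum to 1 so
## constants are preserved; borders clamp-replicate
catmullRomWeights <- function(f) {
  w <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
           ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
  }
  w(f - (-1:2))
}

upsampleMatrix2x <- function(n) {
  M <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    x <- (i - 0.5) / 2 + 0.5       # source coordinate of output centre i
    i0 <- floor(x)
    f <- x - i0
    wts <- catmullRomWeights(f)
    src <- pmin(pmax(i0 + (-1:2), 1L), n)
    for (k in 1:4) M[i, src[k]] <- M[i, src[k]] + wts[k]
  }
  M
}

bicubicUpscale2x <- function(m) {
  My <- upsampleMatrix2x(nrow(m))
  Mx <- upsampleMatrix2x(ncol(m))
  My %*% m %*% t(Mx)
}

## nearest-neighbour 2x upscale (used where interpolation would smear masks)
nnUpscale2x <- function(m) m[rep(seq_len(nrow(m)), each = 2L),
                             rep(seq_len(ncol(m)), each = 2L)]

#' Normalize slice means by a simple ratio
#'
#' Multiplies each slice of a `(y, x, n)` stack by
#' `reference mean / slice mean`, so that all slice means become equal to
#' the reference (the grand mean of slice means by default). This is the
#' flicker/bleaching correction used by the pattern-focus calibration and
#' the optional pseudo-widefield normalization.
#'
#' @param x 3-D array `(y, x, slice)`
#' @param reference target mean intensity; defaults to the grand mean
#' @return list with `data` (normalized array) and `factors` (per-slice
#'   multipliers)
#' @export
normalizeSliceMeans <- function(x, reference = NULL) {
  n <- dim(x)[3L]
  mu <- apply(x, 3L, mean)
  if (any(mu <= 0)) stop("slice means must be positive to normalize")
  if (is.null(reference)) reference <- mean(mu)
  f <- reference / mu
  for (k in seq_len(n)) x[, , k] <- x[, , k] * f[k]
  list(data = x, factors = f)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## per-channel min-max rescale to [0, 1]; constant input maps to 0
rescale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}
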
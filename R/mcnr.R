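## Modulation Contrast-to-Noise: phase-axis discrete Fourier analysis of
## raw SIM data, feature-mean MCNR and Wiener parameter suggestion.

#' Anscombe variance-stabilizing transform
#'
#' `2 * sqrt(x + 3/8)`: maps Poisson-distributed counts to approximately
#' unit-variance Gaussian noise, so that the noise normalization of the
#' modulation-contrast analysis behaves uniformly across intensities.
#'
#' @param x non-negative intensities
#' @return transformed intensities
#' @examples
#' anscombe(0)   # 2*sqrt(3/8)
#' @export
anscombe <- function(x) {
  if (any(x < 0)) stop("Anscombe transform requires non-negative input")
  2 * sqrt(x + 3 / 8)
}

#' Fourier-plane indices of the illumination modulation orders
#'
#' When the raw phase images inside a z-window of half-width `zw` are
#' stacked, the resulting phase series has length `L_FT = P * (2*zw + 1)`,
#' and after a 1-D DFT along that axis the first- and second-order
#' modulation components land exactly at 1-based plane numbers
#' `L_FT * O / P + 1` (the stripe pattern repeats every P planes). The
#' second order requires `P >= 5`; for smaller P it aliases onto the first
#' order and is not reported.
#'
#' @param P number of phase steps (>= 3)
#' @param zw z-window half-width (>= 0)
#' @return list with `L` (series length), `idx1`, `idx2` (1-based DFT plane
#'   numbers; `idx2` is NA when P < 5) and `idxNoise` (the
#'   highest-frequency component used for noise normalization)
#' @examples
#' phaseOrderIndices(5, 1)  # L = 15, orders at planes 4 and 7
#' @export
phaseOrderIndices <- function(P, zw = 1L) {
  P <- as.integer(P); zw <- as.integer(zw)
  if (P < 3L) stop("need at least 3 phase steps")
  if (zw < 0L) stop("z half-width must be >= 0")
  L <- P * (2L * zw + 1L)
  list(L = L,
       idx1 = L %/% P + 1L,
       idx2 = if (P >= 5L) 2L * L %/% P + 1L else NA_integer_,
       idxNoise = floor(L / 2) + 1L)
}

#' Suggested Wiener filter constant from a feature-mean MCNR
#'
#' Empirical suggestion for the regularization constant of the generalized
#' Wiener filter used in SIM reconstruction: `w = 0.17 / MCNR^2`. Higher
#' modulation contrast supports a smaller (sharper) Wiener constant.
#'
#' @param featureMeanMcnr mean feature MCNR (> 0)
#' @return suggested Wiener constant, or NA with a warning when the MCNR is
#'   not positive
#' @examples
#' wienerSuggestion(1)   # 0.17
#' wienerSuggestion(2)   # 0.0425
#' @export
wienerSuggestion <- function(featureMeanMcnr) {
  out <- rep(NA_real_, length(featureMeanMcnr))
  ok <- is.finite(featureMeanMcnr) & featureMeanMcnr > 0
  if (any(featureMeanMcnr <= 0, na.rm = TRUE))
    warning("Wiener suggestion undefined for non-positive MCNR")
  out[ok] <- 0.17 / featureMeanMcnr[ok]^2
  out[is.infinite(featureMeanMcnr) & featureMeanMcnr > 0] <- 0
  out
}

#' Modulation contrast-to-noise ratio check (MCN)
#'
#' Per-voxel measure of the local stripe contrast of raw SIM data relative
#' to noise. For each voxel and angle: (1) Anscombe-transform the raw
#' values; (2) stack the phase images of the `2*zw + 1` neighbouring
#' z-planes (truncated at stack edges) into a phase series of length
#' `L_FT`; (3) 1-D DFT along that series; the modulation amplitudes of
#' order 1 and 2 are read at the plane numbers given by
#' [phaseOrderIndices()], and the highest-frequency component — dominated
#' by noise — is summarized by its standard deviation over the xy-plane.
#' The voxel MCNR is `sqrt(A1^2 + A2^2) / sigma_N`, averaged over angles.
#' The per-channel feature mean is taken over the Otsu foreground of the
#' MCNR map's own stack histogram, and converted to a suggested Wiener
#' constant via [wienerSuggestion()].
#'
#' @param raw a [RawSIMStack] with `P >= 3` (`P >= 5` for the second order)
#' @param zw z-window half-width (default 1, i.e. three z-sections)
#' @param timepoint timepoint to analyse
#' @return an [McnrResult]
#' @export
mcnr <- function(raw, zw = 1L, timepoint = 1L) {
  d <- dim(raw@data)
  C <- d[3]; P <- d[4]; Z <- d[5]; A <- d[6]
  if (P < 3L) stop("MCNR requires at least 3 phase steps")
  Y <- d[1]; X <- d[2]
  map <- array(0, c(Y, X, Z, C))
  sawZeroSigma <- FALSE
  for (c in seq_len(C)) {
    tr <- anscombe(raw@data[, , c, , , , timepoint, drop = FALSE])
    dim(tr) <- c(Y, X, P, Z, A)
    acc <- array(0, c(Y, X, Z))
    for (a in seq_len(A)) for (z in seq_len(Z)) {
      zwin <- max(1L, z - zw):min(Z, z + zw)
      L <- P * length(zwin)
      ## phase series voxel-wise: z-section outer, phase inner
      S <- tr[, , , zwin, a, drop = FALSE]
      dim(S) <- c(Y, X, P, length(zwin))
      S <- aperm(S, c(3, 4, 1, 2))
      dim(S) <- c(L, Y * X)
      basis <- function(k) exp(-2i * pi * (k - 1L) * (0:(L - 1L)) / L)
      A1 <- Mod(basis(L %/% P + 1L) %*% S)
      A2 <- if (P >= 5L) Mod(basis(2L * L %/% P + 1L) %*% S) else 0
      noise <- Mod(basis(floor(L / 2) + 1L) %*% S)
      ## numerical zero: a constant series puts all power at DC
      tol <- L * max(S) * 1e-12
      A1[A1 < tol] <- 0
      if (P >= 5L) A2[A2 < tol] <- 0
      amp <- sqrt(A1^2 + A2^2)
      sigma <- sd(noise)
      if (sigma == 0) {
        ## noise-free input: modulation present -> infinite MCNR sentinel
        sawZeroSigma <- TRUE
        acc[, , z] <- acc[, , z] + matrix(ifelse(amp > 0, Inf, 0), Y, X)
      } else {
        acc[, , z] <- acc[, , z] + matrix(amp / sigma, Y, X)
      }
    }
    map[, , , c] <- acc / A
  }
  if (sawZeroSigma)
    warning("noise-free input: highest-frequency component has zero ",
            "variance; MCNR values are effectively infinite")
  featureMean <- numeric(C); cut <- numeric(C)
  for (c in seq_len(C)) {
    v <- map[, , , c]
    cut[c] <- otsuThreshold(v)
    fg <- v[v > cut[c]]
    featureMean[c] <- if (length(fg)) mean(fg) else NA_real_
  }
  new("McnrResult", map = map, featureMeanMcnr = featureMean,
      wienerSuggestion = wienerSuggestion(featureMean), otsuCut = cut,
      zWindow = as.integer(zw))
}

setMethod("show", "McnrResult", function(object) {
  C <- length(object@featureMeanMcnr)
  cat("Modulation contrast-to-noise (z-window +/-",
      object@zWindow, ")\n", sep = "")
  for (c in seq_len(C))
    cat(sprintf(
      "  ch%d: feature-mean MCNR %.2f (Otsu cut %.2f) -> Wiener w = %.4g\n",
      c, object@featureMeanMcnr[c], object@otsuCut[c],
      object@wienerSuggestion[c]))
})
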
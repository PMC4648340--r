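## Central S4 data containers and per-check result classes.

#' RawSIMStack: a raw structured-illumination acquisition
#'
#' Container for raw 3D-SIM data. The pixel data are held as a 7-dimensional
#' array with dimensions `(y, x, channel, phase, z, angle, time)`; flattening
#' the trailing five dimensions in R's column-major order yields exactly the
#' canonical CPZAT plane sequence (channel varying fastest, then phase, z,
#' angle, time) that all checks assume.
#'
#' @slot data numeric array, `dim = c(Y, X, C, P, Z, A, T)`, intensities >= 0
#' @slot bitDepth camera bit depth (8--32); used to flag saturated pixels
#' @slot pixelXY lateral pixel size in micrometres
#' @slot pixelZ axial step size in micrometres
#' @export
setClass("RawSIMStack",
  slots = c(data = "array", bitDepth = "numeric",
            pixelXY = "numeric", pixelZ = "numeric"))

setValidity("RawSIMStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 7L)
    return("data must be a 7-D array (y, x, c, p, z, a, t)")
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("intensities must be finite")
  if (min(object@data) < 0) return("intensities must be >= 0")
  if (length(object@bitDepth) != 1L ||
      object@bitDepth < 8 || object@bitDepth > 32)
    return("bitDepth must be a single value in [8, 32]")
  if (object@pixelXY <= 0 || object@pixelZ <= 0)
    return("pixel sizes must be positive")
  TRUE
})

#' ReconStack: a reconstructed SIM dataset
#'
#' Container for reconstructed (super-resolution) SIM data, held as a
#' 5-dimensional float array `(y, x, channel, z, time)`. Reconstruction
#' produces 32-bit data with negative ringing around features; several checks
#' (intensity histogram, spherical aberration mismatch) are only meaningful
#' when this full intensity range has not been clipped upstream, which the
#' `fullRange` flag records. When paired with a [RawSIMStack], lateral
#' dimensions are twice the raw dimensions and the pixel size is half.
#'
#' @slot data numeric array, `dim = c(Y, X, C, Z, T)`, finite values
#' @slot pixelXY lateral pixel size in micrometres (half the raw pixel)
#' @slot pixelZ axial step size in micrometres
#' @slot fullRange logical; FALSE if negative/below-mode intensities were
#'   discarded by the reconstruction software
#' @export
setClass("ReconStack",
  slots = c(data = "array", pixelXY = "numeric", pixelZ = "numeric",
            fullRange = "logical"))

setValidity("ReconStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L)
    return("data must be a 5-D array (y, x, c, z, t)")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("values must be finite")
  if (object@pixelXY <= 0 || object@pixelZ <= 0)
    return("pixel sizes must be positive")
  if (length(object@fullRange) != 1L) return("fullRange must be a flag")
  TRUE
})

#' DimensionOrder: plane-sequence ordering of a raw hyperstack
#'
#' A permutation of the letters C, P, Z, A, T naming the axis that varies
#' fastest first along a flattened plane sequence. The canonical ordering is
#' `"CPZAT"` (channel fastest, then phase, z, angle, time).
#'
#' @slot order a 5-character permutation of "CPZAT"
#' @export
setClass("DimensionOrder", slots = c(order = "character"))

setValidity("DimensionOrder", function(object) {
  s <- object@order
  if (length(s) != 1L || nchar(s) != 5L)
    return("order must be one 5-letter string")
  if (!setequal(strsplit(s, "")[[1]], c("C", "P", "Z", "A", "T")))
    return("order must use each of C, P, Z, A, T exactly once")
  TRUE
})

#' CropRegion: a shared crop box for raw and reconstructed stacks
#'
#' Bounds are 0-based and half-open (`x0 <= x < x1`), matching the convention
#' of most imaging toolkits. Applied identically to raw and reconstructed
#' data except that lateral bounds are doubled for the latter.
#'
#' @slot x0,x1,y0,y1 lateral pixel bounds (half-open, 0-based)
#' @slot z0,z1 slice bounds (half-open, 0-based)
#' @export
setClass("CropRegion",
  slots = c(x0 = "integer", x1 = "integer", y0 = "integer", y1 = "integer",
            z0 = "integer", z1 = "integer"))

setValidity("CropRegion", function(object) {
  if (object@x0 < 0 || object@y0 < 0 || object@z0 < 0)
    return("lower bounds must be >= 0")
  if (object@x1 <= object@x0 || object@y1 <= object@y0 ||
      object@z1 <= object@z0)
    return("upper bounds must exceed lower bounds (half-open, non-empty)")
  TRUE
})

#' SimScenario: parameterization of a synthetic SIM acquisition
#'
#' Full description of a simulated raw 3D-SIM acquisition: geometry, striped
#' illumination (spatial frequency, per-angle orientation, modulation depth,
#' axial modulation envelope and focus offset), per-plane degradations
#' (bleaching, flicker, per-angle gain), noise (Poisson shot noise, Gaussian
#' read noise) and camera properties. Serves as ground truth for recovery
#' tests. See [simScenario()] for defaults and units.
#'
#' @slot sizeX,sizeY,sizeZ image dimensions (pixels, slices)
#' @slot nPhases,nAngles,nChannels,nTime dimension counts (P, A, C, T)
#' @slot stripeFreq illumination stripe frequency, cycles/pixel
#' @slot thetaDeg stripe-normal orientation per angle, degrees
#' @slot modDepth modulation depth m in [0, 1]
#' @slot axialPeriodZ axial modulation period, z-slices (Inf = none)
#' @slot focusOffsetZ axial pattern-focus offset, z-slices
#' @slot angleGains per-angle intensity gain (> 0)
#' @slot bleachFraction fractional intensity loss per acquired plane [0, 1)
#' @slot flickerAmp relative slice-to-slice intensity fluctuation (sd)
#' @slot phaseJitterSD per-exposure phase-step error, radians (sd)
#' @slot photonsPerUnit photons per density unit (0 disables Poisson noise)
#' @slot readNoiseSD Gaussian read noise, counts (sd)
#' @slot bitDepth camera bit depth
#' @slot saturate clip at 2^bitDepth - 1 when TRUE
#' @slot snapToGrid round stripe frequency vectors to integer FFT bins
#' @slot pixelXY,pixelZ pixel sizes, micrometres
#' @slot seed RNG seed
#' @export
setClass("SimScenario",
  slots = c(sizeX = "integer", sizeY = "integer", sizeZ = "integer",
            nPhases = "integer", nAngles = "integer",
            nChannels = "integer", nTime = "integer",
            stripeFreq = "numeric", thetaDeg = "numeric",
            modDepth = "numeric", axialPeriodZ = "numeric",
            focusOffsetZ = "numeric", angleGains = "numeric",
            bleachFraction = "numeric", flickerAmp = "numeric",
            phaseJitterSD = "numeric", photonsPerUnit = "numeric",
            readNoiseSD = "numeric", bitDepth = "numeric",
            saturate = "logical", snapToGrid = "logical",
            pixelXY = "numeric", pixelZ = "numeric", seed = "integer"))

setValidity("SimScenario", function(object) {
  if (object@modDepth < 0 || object@modDepth > 1)
    return("modDepth must be in [0, 1]")
  if (any(object@angleGains <= 0)) return("angleGains must be > 0")
  if (object@bleachFraction < 0 || object@bleachFraction >= 1)
    return("bleachFraction must be in [0, 1)")
  if (length(object@thetaDeg) != object@nAngles)
    return("thetaDeg must have one orientation per angle")
  if (length(object@angleGains) != object@nAngles)
    return("angleGains must have one gain per angle")
  if (object@stripeFreq <= 0 || object@stripeFreq >= 0.5)
    return("stripeFreq must lie in (0, 0.5) cycles/pixel")
  TRUE
})

#' CipStats: channel intensity profile summary
#'
#' Per-plane mean intensities (CPZAT order) and the derived intensity
#' statistics, per channel: total intensity variation (TIV) over the central
#' 9-z window, estimated bleaching decay per angle, maximum intensity
#' difference between angles, and slice-to-slice flicker. All percentages.
#'
#' @slot planeMeans matrix, one column per channel, rows in (p, z, a, t) order
#' @slot tiv total intensity variation per channel, percent
#' @slot decayPerAngle matrix (angle x channel), percent lost first-to-last
#' @slot meanDecay per-channel mean decay over angles, percent
#' @slot maxAngleDiff per-channel maximum angle difference, percent
#' @slot flicker per-channel mean relative fluctuation, percent
#' @slot windowZ z-slice range (1-based, inclusive) of the central window
#' @slot nWindowPlanes number of raw images inside the window per channel
#' @export
setClass("CipStats",
  slots = c(planeMeans = "matrix", tiv = "numeric",
            decayPerAngle = "matrix", meanDecay = "numeric",
            maxAngleDiff = "numeric", flicker = "numeric",
            windowZ = "integer", nWindowPlanes = "integer"))

setValidity("CipStats", function(object) {
  if (any(object@tiv < 0 | object@tiv > 100))
    return("tiv must be in [0, 100]")
  if (any(object@flicker < 0 | object@flicker > 100))
    return("flicker must be in [0, 100]")
  TRUE
})

#' McnrResult: modulation contrast-to-noise ratio check output
#'
#' Per-voxel modulation contrast-to-noise ratio (stripe-order Fourier
#' amplitude over the noise-dominated highest-frequency component), averaged
#' over illumination angles, plus per-channel feature statistics: the mean
#' MCNR over Otsu-segmented features and the suggested Wiener filter
#' constant w = 0.17 / MCNR^2 for generalized-Wiener reconstruction.
#'
#' @slot map numeric array (y, x, z, channel) of per-voxel MCNR
#' @slot featureMeanMcnr per-channel mean MCNR over the Otsu foreground
#' @slot wienerSuggestion per-channel suggested Wiener constant
#' @slot otsuCut per-channel Otsu threshold applied to the MCNR map
#' @slot zWindow z half-width used when stacking phase series
#' @export
setClass("McnrResult",
  slots = c(map = "array", featureMeanMcnr = "numeric",
            wienerSuggestion = "numeric", otsuCut = "numeric",
            zWindow = "integer"))

setValidity("McnrResult", function(object) {
  if (any(object@map[is.finite(object@map)] < 0))
    return("MCNR values must be >= 0")
  ok <- is.finite(object@featureMeanMcnr) & object@featureMeanMcnr > 0
  if (any(ok & !(object@wienerSuggestion > 0)))
    return("wienerSuggestion must be > 0 where featureMeanMcnr > 0")
  TRUE
})

#' MivImage: motion and illumination variation false-colour merge
#'
#' Phase-averaged, intensity-normalized per-angle images false-coloured
#' cyan, magenta and yellow and merged to RGB: regions sampled evenly in all
#' three angles appear grey/white, angle-specific intensity (motion,
#' illumination variation) appears coloured.
#'
#' @slot angleImages array (y, x, angle, z) of normalized phase averages
#' @slot rgb array (y, x, 3, z); each colour channel min-max scaled to [0, 1]
#' @export
setClass("MivImage", slots = c(angleImages = "array", rgb = "array"))

setValidity("MivImage", function(object) {
  r <- range(object@rgb)
  if (r[1] < 0 || r[2] > 1) return("rgb channels must be scaled to [0, 1]")
  TRUE
})

#' RihStats: reconstructed intensity histogram summary
#'
#' Histogram of a full-range reconstructed stack with its modal intensity
#' and the means of the extreme tails (Min*, Max*: lowest/highest 0.05% of
#' voxels, at least 100), and the min-to-max ratio
#' MMR = (Max* - Mode) / |Min* - Mode|. A low MMR indicates reconstructed
#' noise/ringing comparable to genuine features.
#'
#' @slot mode modal intensity (tallest bin centre of a 256-bin histogram)
#' @slot minStar,maxStar means of the lowest/highest intensity tails
#' @slot nMin,nMax voxel counts contributing to each tail mean
#' @slot mmr min-to-max ratio (NA if |Min* - Mode| is zero: clipped data)
#' @slot breaks,counts the 256-bin stack histogram
#' @export
setClass("RihStats",
  slots = c(mode = "numeric", minStar = "numeric", maxStar = "numeric",
            nMin = "integer", nMax = "integer", mmr = "numeric",
            breaks = "numeric", counts = "integer"))

#' SamStats: spherical aberration mismatch summary
#'
#' Per-z-slice minima and Otsu-selected feature means, and the z-minimum
#' variation ZMV = sd(slice minima) / mean(feature intensity). Elevated ZMV
#' indicates axial intensity dips from a mismatch between the sample's point
#' spread conditions and the OTF used for reconstruction.
#'
#' @slot minima per-slice minimum intensity
#' @slot featureMeans per-slice mean over Otsu-foreground voxels
#' @slot featureMean grand mean over all Otsu-foreground voxels
#' @slot zmv z-minimum variation (unitless, >= 0)
#' @export
setClass("SamStats",
  slots = c(minima = "numeric", featureMeans = "numeric",
            featureMean = "numeric", zmv = "numeric"))

setValidity("SamStats", function(object) {
  if (is.finite(object@zmv) && object@zmv < 0) return("zmv must be >= 0")
  TRUE
})

#' FourierPlotSet: reconstructed-data Fourier analysis
#'
#' Lateral per-slice amplitude spectra (FTL, gamma-corrected), the axial
#' spectrum of the isotropically resliced central xz-section (FTO), and the
#' radially averaged amplitude profile of the central slice (FTR), together
#' with resolution-ring annotations and the option set used.
#'
#' @slot ftl array (y, x, z) of scaled amplitude spectra (DC centred)
#' @slot fto matrix: axial spectrum of the resliced central xz-section
#' @slot ftr data.frame: radiusPx, freqPerUm, resolutionUm, amplitude
#' @slot rings data.frame: resolutionUm, radiusPx annotation radii
#' @slot options list recording cutoff, window, scaling, gamma, reslice factor
#' @export
setClass("FourierPlotSet",
  slots = c(ftl = "array", fto = "matrix", ftr = "data.frame",
            rings = "data.frame", options = "list"))

#' McmImage: modulation contrast map
#'
#' Reconstructed intensities coloured by the underlying raw-data modulation
#' contrast (heat LUT over MCNR 0..24) and scaled by normalized intensity;
#' voxels saturated in any raw angle/phase are rendered pure green to mark
#' missing stripe information.
#'
#' @slot rgb array (y, x, 3, z) in [0, 1]
#' @slot saturationMask logical array (y, x, z) on the reconstructed grid
#' @export
setClass("McmImage", slots = c(rgb = "array", saturationMask = "array"))

#' IpfMontage: illumination pattern focus calibration view
#'
#' Per-angle orthogonal (xz) maximum-intensity projections along the stripe
#' direction, after slice-mean normalization and rotation of the stripes to
#' vertical. A focused pattern appears as a single bright layer; an axially
#' offset pattern produces a staggered "zipper" appearance.
#'
#' @slot panels list of Z-by-X matrices, one per angle
#' @slot montage the panels stacked into one matrix on a shared scale
#' @slot thetaDeg estimated stripe-normal orientation per angle, degrees
#' @slot normFactors list of per-slice normalization factors per angle
#' @export
setClass("IpfMontage",
  slots = c(panels = "list", montage = "matrix", thetaDeg = "numeric",
            normFactors = "list"))

#' IpsResult: illumination phase step calibration statistics
#'
#' First-order illumination peak positions in frequency space and the
#' unwrapped phase series measured at them, per angle, with summary
#' statistics: the mean recovered phase step, the standard deviation of
#' successive phase steps (step accuracy), and the standard deviation of the
#' residual offsets (offset stability). Radians throughout. The sign
#' convention is that of the detected spectral peak; use the magnitude of
#' `meanStep` to compare with the nominal step 2*pi/P.
#'
#' @slot peaks matrix (angle x 2): frequency-pixel positions (kx, ky), cycles
#' @slot phaseSeries list per angle: matrix (P x nZ) of unwrapped phases
#' @slot meanStep per-angle mean successive phase step, radians
#' @slot stepSD per-angle phase step standard deviation, radians
#' @slot offsetSD per-angle phase offset standard deviation, radians
#' @slot zUsed z-slices analysed (1-based)
#' @export
setClass("IpsResult",
  slots = c(peaks = "matrix", phaseSeries = "list", meanStep = "numeric",
            stepSD = "numeric", offsetSD = "numeric", zUsed = "integer"))

setValidity("IpsResult", function(object) {
  if (any(object@stepSD < 0) || any(object@offsetSD < 0))
    return("standard deviations must be >= 0")
  TRUE
})

#' CheckReport: one quality check's metrics, tiers and artifacts
#'
#' @slot checkId short identifier (e.g. "cip", "mcn", "rih")
#' @slot title human-readable check name
#' @slot metrics named list of scalar metric values
#' @slot units named character vector of metric units
#' @slot tiers named character vector: "ok", "caution" or "concern" per
#'   metric, derived from configurable thresholds only
#' @slot guidance interpretation hint for this check's result
#' @slot artifacts paths of rendered output files (possibly empty)
#' @export
setClass("CheckReport",
  slots = c(checkId = "character", title = "character", metrics = "list",
            units = "character", tiers = "character", guidance = "character",
            artifacts = "character"))

setValidity("CheckReport", function(object) {
  if (!all(names(object@metrics) %in% names(object@tiers)))
    return("every metric must have a tier")
  if (!all(object@tiers %in% c("ok", "caution", "concern", "na")))
    return("tiers must be ok/caution/concern/na")
  TRUE
})
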
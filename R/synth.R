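## Synthetic raw-SIM acquisition simulator with known ground truth.

#' Define a synthetic SIM acquisition scenario
#'
#' Parameterizes the image-formation model used by [generateRawSIM()]:
#' each raw plane `(a, p, z)` is
#' `gain_a * (1 - b)^acq * (1 + f*eta) * density(z) * I_ap(x, y, z)` with the
#' striped illumination
#' `I_ap = 1 + m * M(z - dz) * cos(2*pi*k*(x*cos(theta_a) + y*sin(theta_a)) + phi_p)`,
#' `phi_p = 2*pi*(p-1)/P` (plus optional per-exposure jitter) and an axial
#' modulation envelope `M(z') = cos(2*pi*z'/Tz)` (`M = 1` when
#' `axialPeriodZ = Inf`). Poisson shot noise, Gaussian read noise and
#' saturation clipping are applied afterwards. The acquisition index for
#' bleaching follows the CPZAT plane sequence, so bleaching couples to the
#' phase-within-z-within-angle acquisition loop exactly as the intensity
#' profile check expects.
#'
#' Defaults describe a typical small 3D-SIM acquisition: a 64 x 64 x 9
#' field, 5 phases x 3 angles (orientations 60 degrees apart, offset from
#' the pixel axes as on real instruments), stripe frequency 0.19
#' cycles/pixel (a ~0.42 um pattern period at 0.08 um pixels), modulation
#' depth 0.8, and modest camera noise.
#'
#' @param sizeX,sizeY,sizeZ image dimensions
#' @param nPhases,nAngles,nChannels,nTime dimension counts
#' @param stripeFreq stripe frequency, cycles/pixel
#' @param thetaDeg stripe-normal orientations, degrees (length `nAngles`)
#' @param modDepth modulation depth m in [0, 1]
#' @param axialPeriodZ axial envelope period in z-slices (Inf disables)
#' @param focusOffsetZ axial pattern-focus offset dz, z-slices
#' @param angleGains per-angle gains
#' @param bleachFraction per-plane fractional bleaching b in [0, 1)
#' @param flickerAmp relative sd of per-plane intensity fluctuation
#' @param phaseJitterSD sd of per-exposure phase error, radians
#' @param photonsPerUnit photons per density unit (0 = no Poisson noise)
#' @param readNoiseSD Gaussian read noise sd, counts
#' @param bitDepth camera bit depth
#' @param saturate clip at `2^bitDepth - 1`
#' @param snapToGrid round each angle's frequency vector to integer FFT
#'   bins so stripes are exactly periodic on the grid (default TRUE)
#' @param pixelXY,pixelZ pixel sizes, micrometres
#' @param seed RNG seed
#' @return a [SimScenario]
#' @export
simScenario <- function(sizeX = 64L, sizeY = 64L, sizeZ = 9L,
                        nPhases = 5L, nAngles = 3L, nChannels = 1L,
                        nTime = 1L, stripeFreq = 0.19,
                        thetaDeg = c(15, 75, 135)[seq_len(nAngles)],
                        modDepth = 0.8, axialPeriodZ = Inf,
                        focusOffsetZ = 0, angleGains = rep(1, nAngles),
                        bleachFraction = 0, flickerAmp = 0,
                        phaseJitterSD = 0, photonsPerUnit = 0,
                        readNoiseSD = 0, bitDepth = 15, saturate = FALSE,
                        snapToGrid = TRUE, pixelXY = 0.08, pixelZ = 0.125,
                        seed = 1L) {
  new("SimScenario", sizeX = as.integer(sizeX), sizeY = as.integer(sizeY),
      sizeZ = as.integer(sizeZ), nPhases = as.integer(nPhases),
      nAngles = as.integer(nAngles), nChannels = as.integer(nChannels),
      nTime = as.integer(nTime), stripeFreq = stripeFreq,
      thetaDeg = thetaDeg, modDepth = modDepth,
      axialPeriodZ = axialPeriodZ, focusOffsetZ = focusOffsetZ,
      angleGains = angleGains, bleachFraction = bleachFraction,
      flickerAmp = flickerAmp, phaseJitterSD = phaseJitterSD,
      photonsPerUnit = photonsPerUnit, readNoiseSD = readNoiseSD,
      bitDepth = bitDepth, saturate = saturate, snapToGrid = snapToGrid,
      pixelXY = pixelXY, pixelZ = pixelZ, seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf("SimScenario: %d x %d x %d, P=%d A=%d C=%d T=%d\n",
              object@sizeX, object@sizeY, object@sizeZ, object@nPhases,
              object@nAngles, object@nChannels, object@nTime))
  cat(sprintf("  stripes: k=%.3f cyc/px, m=%.2f, theta=%s deg\n",
              object@stripeFreq, object@modDepth,
              paste(object@thetaDeg, collapse = "/")))
  cat(sprintf(
    "  axial period=%s dz=%g | gains=%s bleach=%g flicker=%g jitter=%g\n",
    format(object@axialPeriodZ), object@focusOffsetZ,
    paste(object@angleGains, collapse = "/"), object@bleachFraction,
    object@flickerAmp, object@phaseJitterSD))
  cat(sprintf("  noise: photons/unit=%g read sd=%g | %g-bit%s seed=%d\n",
              object@photonsPerUnit, object@readNoiseSD, object@bitDepth,
              if (object@saturate) " (saturating)" else "", object@seed))
})

#' Generate a blurred bead field
#'
#' Places `nBeads` sub-resolution fluorescent beads uniformly at random in
#' the volume (or all in one z-layer) and renders each as a 3-D Gaussian of
#' total flux `flux`, emulating point sources blurred by the microscope
#' point spread function.
#'
#' @param sizeX,sizeY,sizeZ volume dimensions
#' @param nBeads number of beads (>= 0)
#' @param psfSigmaXY,psfSigmaZ Gaussian blur sigmas, pixels/slices (> 0)
#' @param flux photons per bead
#' @param layerZ if non-NULL, place all beads at this z (bead-lawn layout)
#' @param uniform if TRUE, replace the beads by a spatially uniform sheet
#'   of equal total flux at `layerZ` (the ideal dense-lawn limit used by the
#'   calibration tools)
#' @param margin keep bead centres this many pixels away from the lateral
#'   borders (limits boundary flux loss)
#' @param seed RNG seed
#' @return 3-D array `(y, x, z)` of fluorophore density; its sum is close
#'   to `nBeads * flux` (Gaussian tails beyond the volume are lost)
#' @export
generateBeadField <- function(sizeX = 64L, sizeY = 64L, sizeZ = 9L,
                              nBeads = 50L, psfSigmaXY = 1.5,
                              psfSigmaZ = 1.2, flux = 1000,
                              layerZ = NULL, uniform = FALSE,
                              margin = 3, seed = 1L) {
  if (psfSigmaXY <= 0 || psfSigmaZ <= 0) stop("psf sigma must be > 0")
  if (nBeads < 0) stop("nBeads must be >= 0")
  vol <- array(0, c(sizeY, sizeX, sizeZ))
  if (uniform) {
    z0 <- if (is.null(layerZ)) (sizeZ + 1) / 2 else layerZ
    zprof <- exp(-0.5 * ((seq_len(sizeZ) - z0) / psfSigmaZ)^2)
    zprof <- zprof / sum(zprof)
    level <- nBeads * flux / (sizeX * sizeY)
    for (z in seq_len(sizeZ)) vol[, , z] <- level * zprof[z]
    return(vol)
  }
  if (nBeads == 0L) return(vol)
  set.seed(seed)
  bx <- runif(nBeads, 1 + margin, sizeX - margin)
  by <- runif(nBeads, 1 + margin, sizeY - margin)
  bz <- if (is.null(layerZ)) runif(nBeads, 1, sizeZ) else rep(layerZ, nBeads)
  xs <- seq_len(sizeX); ys <- seq_len(sizeY); zs <- seq_len(sizeZ)
  normXY <- 1 / (2 * pi * psfSigmaXY^2)
  normZ <- 1 / sqrt(2 * pi * psfSigmaZ^2)
  for (b in seq_len(nBeads)) {
    gx <- exp(-0.5 * ((xs - bx[b]) / psfSigmaXY)^2)
    gy <- exp(-0.5 * ((ys - by[b]) / psfSigmaXY)^2)
    gz <- exp(-0.5 * ((zs - bz[b]) / psfSigmaZ)^2)
    blob <- flux * normXY * normZ * outer(gy, gx)
    for (z in zs) vol[, , z] <- vol[, , z] + blob * gz[z]
  }
  vol
}

## per-angle frequency vector in cycles/pixel, optionally snapped to
## integer FFT bins of the (sizeY, sizeX) grid
angleFreqVector <- function(scenario, a) {
  th <- scenario@thetaDeg[a] * pi / 180
  kx <- scenario@stripeFreq * cos(th)
  ky <- scenario@stripeFreq * sin(th)
  if (scenario@snapToGrid) {
    kx <- round(kx * scenario@sizeX) / scenario@sizeX
    ky <- round(ky * scenario@sizeY) / scenario@sizeY
  }
  c(kx = kx, ky = ky)
}

#' Simulate a raw SIM acquisition
#'
#' Applies the striped-illumination image-formation model of a
#' [SimScenario] to a fluorophore density (e.g. from
#' [generateBeadField()]), returning the raw hyperstack and the exact
#' ground truth behind it. The illumination multiplies the already-blurred
#' density, so the nominal modulation depth `m` is preserved exactly in the
#' noise-free stripes (convenient for recovery tests; a physical microscope
#' would attenuate stripe contrast through the detection PSF).
#'
#' @param density 3-D array `(y, x, z)` (recycled across channels) or 4-D
#'   `(y, x, z, c)`
#' @param scenario a [SimScenario]
#' @return list with `stack` (a [RawSIMStack]) and `truth`: bead/sheet
#'   density, per-angle frequency vectors (cycles/pixel), exact phase list
#'   `phases[p, z, a]` (radians), modulation depth, focus offset, per-plane
#'   expected mean intensity (no-noise), and the acquisition-order bleach
#'   factors
#' @export
generateRawSIM <- function(density, scenario) {
  sc <- scenario
  Y <- sc@sizeY; X <- sc@sizeX; Z <- sc@sizeZ
  P <- sc@nPhases; A <- sc@nAngles; C <- sc@nChannels; TT <- sc@nTime
  if (length(dim(density)) == 3L)
    density <- array(density, c(dim(density), 1L))
  if (!all(dim(density)[1:3] == c(Y, X, Z)))
    stop("density dimensions ", paste(dim(density)[1:3], collapse = "x"),
         " do not match scenario ", Y, "x", X, "x", Z)
  set.seed(sc@seed)
  phases <- array(2 * pi * (rep(seq_len(P), Z * A) - 1) / P, c(P, Z, A))
  if (sc@phaseJitterSD > 0)
    phases <- phases + array(rnorm(P * Z * A, 0, sc@phaseJitterSD),
                             c(P, Z, A))
  kvec <- t(vapply(seq_len(A), function(a) angleFreqVector(sc, a),
                   c(kx = 0, ky = 0)))
  xg <- matrix(0:(X - 1), Y, X, byrow = TRUE)
  yg <- matrix(0:(Y - 1), Y, X)
  zc <- (Z + 1) / 2
  Mz <- if (is.finite(sc@axialPeriodZ))
    cos(2 * pi * (seq_len(Z) - zc - sc@focusOffsetZ) / sc@axialPeriodZ)
  else rep(1, Z)
  satLevel <- 2^sc@bitDepth - 1
  anyNoise <- sc@photonsPerUnit > 0 || sc@readNoiseSD > 0
  data <- array(0, c(Y, X, C, P, Z, A, TT))
  expectedMeans <- array(0, c(C, P, Z, A, TT))
  bleachIdx <- function(c, p, z, a, t)
    (p - 1) + P * ((z - 1) + Z * ((a - 1) + A * (t - 1)))
  for (t in seq_len(TT)) for (a in seq_len(A)) for (z in seq_len(Z)) {
    carrier <- 2 * pi * (kvec[a, "kx"] * xg + kvec[a, "ky"] * yg)
    for (p in seq_len(P)) for (c in seq_len(C)) {
      illum <- 1 + sc@modDepth * Mz[z] * cos(carrier + phases[p, z, a])
      idx <- bleachIdx(c, p, z, a, t)
      base <- sc@angleGains[a] * (1 - sc@bleachFraction)^idx *
        density[, , z, c] * illum
      expectedMeans[c, p, z, a, t] <- mean(base) *
        max(sc@photonsPerUnit, 1)
      if (sc@flickerAmp > 0)
        base <- base * (1 + sc@flickerAmp * rnorm(1))
      plane <- if (sc@photonsPerUnit > 0)
        matrix(rpois(Y * X, pmax(base, 0) * sc@photonsPerUnit), Y, X)
      else base
      if (sc@readNoiseSD > 0)
        plane <- plane + matrix(rnorm(Y * X, 0, sc@readNoiseSD), Y, X)
      if (anyNoise) plane <- round(plane)
      plane <- pmax(plane, 0)
      if (sc@saturate) plane <- pmin(plane, satLevel)
      data[, , c, p, z, a, t] <- plane
    }
  }
  stack <- new("RawSIMStack", data = data, bitDepth = sc@bitDepth,
               pixelXY = sc@pixelXY, pixelZ = sc@pixelZ)
  list(stack = stack,
       truth = list(density = density, freqVectors = kvec, phases = phases,
                    modDepth = sc@modDepth, focusOffsetZ = sc@focusOffsetZ,
                    axialEnvelope = Mz, expectedMeans = expectedMeans,
                    scenario = sc))
}

#' Generate a reconstruction-like stack with known histogram tails
#'
#' Produces a full-range float stack that mimics the statistical signature
#' of reconstructed SIM data — a histogram mode near zero from background
#' noise, bright features, and negative ringing lobes — without running a
#' reconstruction. Two modes:
#'
#' * `density` given: the density is bicubically upscaled 2x laterally,
#'   negative axial side lobes of relative amplitude `ringingAmp` are
#'   subtracted at `ringingShiftZ` slices above and below each feature, and
#'   zero-mean Gaussian background noise is added.
#' * `dim` given (no density): a noise background with exactly `nFeature`
#'   voxels implanted at `featureValue` and `nRinging` voxels at
#'   `ringingValue` — the histogram tails are then known by construction.
#'
#' @param density optional 3-D array `(y, x, z)` of features
#' @param dim integer `c(Y, X, Z)` for the constructed-tails mode
#' @param noiseSD background noise sd
#' @param ringingAmp relative amplitude of negative axial side lobes
#' @param ringingShiftZ axial offset of the side lobes, slices
#' @param nFeature,featureValue,nRinging,ringingValue implanted tails
#' @param pixelXY,pixelZ pixel sizes, micrometres
#' @param seed RNG seed
#' @return a [ReconStack] (`fullRange = TRUE`)
#' @export
generateReconLike <- function(density = NULL, dim = NULL, noiseSD = 0.1,
                              ringingAmp = 0, ringingShiftZ = 1L,
                              nFeature = 0L, featureValue = 100,
                              nRinging = 0L, ringingValue = -50,
                              pixelXY = 0.04, pixelZ = 0.125, seed = 1L) {
  if (ringingAmp < 0) stop("ringingAmp must be >= 0")
  set.seed(seed)
  if (!is.null(density)) {
    d <- base::dim(density)
    Z <- d[3]
    up <- array(0, c(2L * d[1], 2L * d[2], Z))
    for (z in seq_len(Z)) up[, , z] <- pmax(bicubicUpscale2x(density[, , z]), 0)
    out <- up
    if (ringingAmp > 0) {
      s <- as.integer(ringingShiftZ)
      for (z in seq_len(Z)) {
        if (z - s >= 1) out[, , z - s] <- out[, , z - s] - ringingAmp * up[, , z]
        if (z + s <= Z) out[, , z + s] <- out[, , z + s] - ringingAmp * up[, , z]
      }
    }
    if (noiseSD > 0)
      out <- out + array(rnorm(length(out), 0, noiseSD), base::dim(out))
    return(ReconStack(out, pixelXY = pixelXY, pixelZ = pixelZ,
                      fullRange = TRUE))
  }
  if (is.null(dim)) stop("supply density or dim")
  n <- prod(dim)
  v <- rnorm(n, 0, noiseSD)
  pick <- sample.int(n, nFeature + nRinging)
  if (nFeature > 0) v[pick[seq_len(nFeature)]] <- featureValue
  if (nRinging > 0) v[pick[nFeature + seq_len(nRinging)]] <- ringingValue
  ReconStack(array(v, dim), pixelXY = pixelXY, pixelZ = pixelZ,
             fullRange = TRUE)
}

#' Emulate a reconstruction of a scenario's sample
#'
#' Maps a [SimScenario]'s axial pattern-focus offset to the depth of the
#' negative axial side lobes that such a mismatch produces in real
#' reconstructions (deeper intensity dips below/above the feature layer for
#' larger offsets), then builds the corresponding reconstruction-like stack
#' via [generateReconLike()]. This is a phenomenological emulation for
#' testing the spherical-aberration-mismatch check — no reconstruction is
#' performed.
#'
#' @param scenario a [SimScenario]
#' @param density 3-D feature density on the raw grid
#' @param baseRinging side-lobe amplitude at zero offset
#' @param mismatchGain additional amplitude per z-slice of focus offset
#' @param noiseSD background noise sd
#' @param seed RNG seed
#' @return a [ReconStack]
#' @export
reconFromScenario <- function(scenario, density, baseRinging = 0.05,
                              mismatchGain = 0.15, noiseSD = 0.5,
                              seed = 1L) {
  amp <- baseRinging + mismatchGain * abs(scenario@focusOffsetZ)
  generateReconLike(density = density, noiseSD = noiseSD, ringingAmp = amp,
                    pixelXY = scenario@pixelXY / 2, pixelZ = scenario@pixelZ,
                    seed = seed)
}
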
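## Fixture builders shared across the suite. Everything is generated in
## code; no binary fixtures.

## constant-intensity raw stack
constRaw <- function(value = 5, Y = 8, X = 8, C = 1, P = 5, Z = 9, A = 3,
                     T = 1, bitDepth = 15) {
  RawSIMStack(array(value, c(Y, X, C, P, Z, A, T)), bitDepth = bitDepth)
}

## raw stack whose plane means follow `means` (CPZAT order, single channel)
rampRaw <- function(means, Y = 6, X = 6, P = 5, Z = 9, A = 3) {
  stopifnot(length(means) == P * Z * A)
  arr <- array(0, c(Y, X, 1, P, Z, A, 1))
  i <- 0
  for (a in seq_len(A)) for (z in seq_len(Z)) for (p in seq_len(P)) {
    i <- i + 1
    arr[, , 1, p, z, a, 1] <- means[i]
  }
  RawSIMStack(arr)
}

## small noisy bead scenario for integration-style checks
noisyBeadSim <- function(m = 0.5, seed = 7, sizeXY = 32, Z = 5,
                         photons = 1, readNoise = 2, flux = 3000) {
  sc <- simScenario(sizeX = sizeXY, sizeY = sizeXY, sizeZ = Z,
                    modDepth = m, photonsPerUnit = photons,
                    readNoiseSD = readNoise, seed = seed)
  dens <- generateBeadField(sizeXY, sizeXY, Z, nBeads = 30, flux = flux,
                            seed = 5)
  generateRawSIM(dens, sc)
}

## uniform-sheet calibration sample (ideal dense bead lawn)
sheetSim <- function(modDepth = 0.9, sizeXY = 64, Z = 5, layerZ = 3,
                     phaseJitterSD = 0, seed = 1, stripeFreq = 0.19,
                     axialPeriodZ = Inf, focusOffsetZ = 0,
                     nPhases = 5) {
  sc <- simScenario(sizeX = sizeXY, sizeY = sizeXY, sizeZ = Z,
                    nPhases = nPhases, modDepth = modDepth,
                    phaseJitterSD = phaseJitterSD,
                    axialPeriodZ = axialPeriodZ,
                    focusOffsetZ = focusOffsetZ,
                    stripeFreq = stripeFreq, seed = seed)
  dens <- generateBeadField(sizeXY, sizeXY, Z, nBeads = 300,
                            uniform = TRUE, layerZ = layerZ,
                            psfSigmaZ = 1.5, seed = 1)
  generateRawSIM(dens, sc)
}

## constructed recon stack for the MMR oracle: exact -50/+100 tails over a
## near-zero background
mmrOracleRecon <- function(n = c(50, 50, 40), seed = 2) {
  generateReconLike(dim = n, noiseSD = 0.1, nFeature = 100,
                    featureValue = 100, nRinging = 100,
                    ringingValue = -50, seed = seed)
}

## constructed recon stack with known slice minima and a bright feature
## block: background 10, features 100, one pixel per slice carries the
## minimum
samOracleRecon <- function(minima) {
  Z <- length(minima)
  v <- array(10, c(20, 20, Z))
  for (z in seq_len(Z)) {
    v[1, 1, z] <- minima[z]
    v[5:10, 5:10, z] <- 100
  }
  ReconStack(v)
}

## all permutations of the CPZAT letters (5! = 120)
allOrderStrings <- function() {
  perm <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  vapply(perm(c("C", "P", "Z", "A", "T")), paste, "", collapse = "")
}

## test-side oracle: given a canonical CPZAT plane sequence, produce the
## sequence as it would be stored under `ord` (fastest-first), by
## independent mixed-radix index arithmetic
storeInOrder <- function(planesCPZAT, ord, dims) {
  letters5 <- strsplit(ord, "")[[1]]
  n <- prod(dims)
  sizes <- dims[letters5]
  out <- planesCPZAT
  C <- dims[["C"]]; P <- dims[["P"]]; Z <- dims[["Z"]]; A <- dims[["A"]]
  for (j in 0:(n - 1L)) {
    rem <- j; coord <- integer(5); names(coord) <- letters5
    for (k in 1:5) { coord[k] <- rem %% sizes[k]; rem <- rem %/% sizes[k] }
    target <- coord[["C"]] + C * (coord[["P"]] + P * (coord[["Z"]] +
                Z * (coord[["A"]] + A * coord[["T"]])))
    out[, , j + 1L] <- planesCPZAT[, , target + 1L]
  }
  out
}
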
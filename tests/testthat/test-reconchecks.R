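test_that("the constructed-tails stack yields MMR near 2 and exact tail means", {
  rih <- reconstructedIntensityHistogram(mmrOracleRecon())
  expect_equal(rih@minStar, -50)
  expect_equal(rih@maxStar, 100)
  expect_lt(abs(rih@mode), 0.3)                  # background mode ~0
  expect_equal(rih@mmr, 2, tolerance = 0.01)
  ## tail size: max(0.0005 * 1e5, 100) = 100
  expect_identical(rih@nMin, 100L)
  expect_identical(rih@nMax, 100L)
})

test_that("tails symmetric about the mode give MMR = 1 and clipped data warns", {
  rc <- generateReconLike(dim = c(40, 40, 40), noiseSD = 0.1,
                          nFeature = 100, featureValue = 50,
                          nRinging = 100, ringingValue = -50, seed = 4)
  rih <- reconstructedIntensityHistogram(rc)
  expect_equal(rih@mmr, 1, tolerance = 0.02)
  clipped <- ReconStack(pmax(stackData(rc), 0), fullRange = FALSE)
  expect_warning(reconstructedIntensityHistogram(clipped), "full")
})

test_that("MMR is invariant under an affine intensity shift", {
  rc <- mmrOracleRecon(seed = 5)
  a <- reconstructedIntensityHistogram(rc)
  shifted <- ReconStack(stackData(rc) + 123.4)
  b <- reconstructedIntensityHistogram(shifted)
  expect_equal(a@mmr, b@mmr, tolerance = 1e-9)
  expect_equal(b@mode - a@mode, 123.4, tolerance = 1e-9)
})

test_that("ZMV is zero for z-invariant stacks and matches its definition exactly", {
  flat <- samOracleRecon(rep(2, 9))
  expect_equal(sphericalAberrationMismatch(flat)@zmv, 0)
  minima <- c(0, 1.5, 3, 4.5, 6, 7.5, 9, 8, 7)   # all below background 10
  sam <- sphericalAberrationMismatch(samOracleRecon(minima))
  expect_equal(sam@zmv, sd(minima) / 100, tolerance = 1e-9)
  expect_equal(sam@minima, minima)
  expect_equal(sam@featureMean, 100)
})

test_that("ZMV is invariant under global positive scaling", {
  sam1 <- sphericalAberrationMismatch(samOracleRecon(c(0, 2, 4, 6, 8)))
  scaled <- ReconStack(stackData(samOracleRecon(c(0, 2, 4, 6, 8))) * 3.7)
  sam2 <- sphericalAberrationMismatch(scaled)
  expect_equal(sam1@zmv, sam2@zmv, tolerance = 1e-12)
})

test_that("axially offset pattern focus produces larger ZMV than matched focus", {
  for (s in 1:3) {
    dens <- generateBeadField(24, 24, 9, nBeads = 60, layerZ = 5,
                              psfSigmaZ = 1, seed = s)
    matched <- reconFromScenario(simScenario(sizeZ = 9, focusOffsetZ = 0),
                                 dens, seed = s)
    offset <- reconFromScenario(simScenario(sizeZ = 9, focusOffsetZ = 3),
                                dens, seed = s)
    zmvM <- sphericalAberrationMismatch(matched)@zmv
    zmvO <- sphericalAberrationMismatch(offset)@zmv
    expect_gt(zmvO, zmvM)
  }
})

test_that("Fourier plots annotate rings and reslice to isotropic voxels correctly", {
  v <- array(0, c(64, 64, 5)); v[33, 33, 3] <- 1   # centred impulse
  rec <- ReconStack(v, pixelXY = 0.04, pixelZ = 0.125)
  fps <- fourierPlots(rec, cutoff = NULL)
  ## impulse: flat amplitude spectrum, constant radial profile
  expect_lt(diff(range(fps@ftr$amplitude, na.rm = TRUE)), 1e-9)
  ## ring radius X * pixel / d
  expect_equal(fps@rings$radiusPx,
               64 * 0.04 / c(0.2, 0.13, 0.1), tolerance = 1e-12)
  expect_equal(fps@options$resliceFactor, 3.125)
  expect_identical(nrow(fps@ftr), 32L)            # floor(X/2) bins
})

test_that("the automatic cutoff zeroes exactly the below-mode fraction", {
  rc <- generateReconLike(dim = c(40, 40, 8), noiseSD = 1, nFeature = 60,
                          featureValue = 50, seed = 6)
  v <- stackData(rc)[, , 1, , 1]
  m <- simqc:::stackMode(v)
  fps <- fourierPlots(rc, cutoff = "auto")
  expect_equal(fps@options$cutoff, m)
  ## reproduce the pre-processing and compare fractions
  expect_identical(mean(pmax(v - m, 0) == 0), mean(v <= m))
})

test_that("the radial profile of white noise is flat beyond the DC bins", {
  profs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    rec <- ReconStack(array(rnorm(64 * 64, 100, 5), c(64, 64, 1)))
    fourierPlots(rec, cutoff = NULL)@ftr$amplitude
  })
  avg <- rowMeans(profs)
  core <- avg[8:30]                              # past cutoff-affected DC
  expect_lt(max(abs(core - median(core))) / median(core), 0.05)
})

test_that("log-power scaling rescales each slice between mode and max", {
  rc <- generateReconLike(dim = c(32, 32, 3), noiseSD = 1, nFeature = 20,
                          featureValue = 40, seed = 7)
  fps <- fourierPlots(rc, scaling = "log")
  expect_gte(min(fps@ftl), 0)
  expect_lte(max(fps@ftl), 1)
})

test_that("the modulation contrast map colours saturation green and zero intensity black", {
  sim <- noisyBeadSim(m = 0.5, seed = 9, sizeXY = 16, Z = 3)
  raw <- sim$stack
  raw@data[4, 4, 1, 1, 2, 1, 1] <- 2^15 - 1
  res <- mcnr(raw)
  set.seed(20)
  recon <- ReconStack(array(runif(32 * 32 * 3, 0.5, 1), c(32, 32, 3)))
  mcm <- modulationContrastMap(recon, res, raw)
  expect_identical(sum(mcm@saturationMask), 4L)   # 2x2 nearest-neighbour
  px <- mcm@rgb[7, 7, , 2]
  expect_identical(px[c(1, 3)], c(0, 0))
  expect_gt(px[2], 0)
  ## black where the reconstruction is zero
  dark <- modulationContrastMap(ReconStack(array(0, c(32, 32, 3))), res, raw)
  expect_identical(max(dark@rgb), 0)
  ## uniform MCNR and intensity give one uniform colour
  uni <- res
  uni@map[] <- 6
  rawU <- RawSIMStack(array(10, c(16, 16, 1, 5, 3, 3, 1)), bitDepth = 15)
  flat <- modulationContrastMap(ReconStack(array(2, c(32, 32, 3))), uni, rawU)
  for (ch in 1:3) expect_equal(diff(range(flat@rgb[, , ch, ])), 0)
  ## shape guard
  expect_error(modulationContrastMap(ReconStack(array(0, c(30, 30, 3))),
                                     res, raw), "2x")
})
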
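test_that("slice-mean normalization equalizes slice means exactly", {
  set.seed(30)
  x <- array(runif(8 * 8 * 5, 10, 50), c(8, 8, 5))
  nrm <- normalizeSliceMeans(x)
  mu <- apply(nrm$data, 3, mean)
  expect_lt(diff(range(mu)), 1e-9)
})

test_that("a focused pattern projects a single layer at the sample plane, an offset one shifts by dz", {
  mk <- function(dz) sheetSim(modDepth = 1, sizeXY = 48, Z = 15,
                              layerZ = 8, axialPeriodZ = 30,
                              focusOffsetZ = dz, stripeFreq = 0.2)$stack
  brightPeak <- function(ipf) {
    p <- ipf@panels[[1]]
    bright <- which(apply(p, 2, max) >= stats::quantile(apply(p, 2, max),
                                                        0.75))
    median(apply(p[, bright, drop = FALSE], 2, which.max))
  }
  ipf0 <- illuminationPatternFocus(mk(0))
  ipf3 <- illuminationPatternFocus(mk(3))
  expect_lt(abs(brightPeak(ipf0) - 8), 0.51)
  expect_equal(brightPeak(ipf3) - brightPeak(ipf0), 3, tolerance = 0.55)
  ## zipper: opposite-phase columns peak at a different z than bright ones
  p3 <- ipf3@panels[[1]]
  colPeaks <- apply(p3, 2, which.max)
  expect_gt(diff(range(colPeaks)), 2)
})

test_that("the IPF axial peak is invariant to in-plane rotation of the scenario", {
  mk <- function(extraTheta) {
    sc <- simScenario(sizeX = 48, sizeY = 48, sizeZ = 9, modDepth = 1,
                      axialPeriodZ = 18, stripeFreq = 0.2,
                      thetaDeg = c(20, 80, 140) + extraTheta)
    dens <- generateBeadField(48, 48, 9, nBeads = 300, uniform = TRUE,
                              layerZ = 5, psfSigmaZ = 1.5, seed = 1)
    generateRawSIM(dens, sc)$stack
  }
  peakOf <- function(stack) {
    p <- illuminationPatternFocus(stack)@panels[[1]]
    bright <- which(apply(p, 2, max) >= stats::quantile(apply(p, 2, max),
                                                        0.75))
    median(apply(p[, bright, drop = FALSE], 2, which.max))
  }
  expect_equal(peakOf(mk(0)), peakOf(mk(25)), tolerance = 1)
})

test_that("exact generators give exact phase steps for 3 and 5 phases", {
  for (P in c(3L, 5L)) {
    sim <- sheetSim(nPhases = P, Z = 5, layerZ = 3)
    ips <- illuminationPhaseSteps(sim$stack, zRange = 1)
    expect_equal(abs(ips@meanStep), rep(2 * pi / P, 3), tolerance = 1e-6)
    expect_true(all(ips@stepSD < 1e-6))
    expect_true(all(ips@offsetSD < 1e-6))
    ## detected peak equals the generator's frequency vector within one
    ## frequency pixel (up to the conjugate pair)
    kv <- sim$truth$freqVectors
    for (a in 1:3) {
      dk <- min(max(abs(ips@peaks[a, ] - kv[a, ])),
                max(abs(ips@peaks[a, ] + kv[a, ])))
      expect_lt(dk, 1 / 64 + 1e-12)
    }
  }
})

test_that("phase estimates are invariant under global intensity scaling", {
  sim <- sheetSim(Z = 3, layerZ = 2)
  raw <- sim$stack
  ips1 <- illuminationPhaseSteps(raw, zRange = 0)
  ips2 <- illuminationPhaseSteps(
    RawSIMStack(stackData(raw) * 40, bitDepth = 32), zRange = 0)
  expect_equal(ips1@phaseSeries, ips2@phaseSeries, tolerance = 1e-9)
})

test_that("injected phase jitter is recovered at the expected magnitude", {
  ## sd of successive step differences for iid jitter sigma is sigma*sqrt(2)
  recovered <- vapply(1:10, function(s) {
    sim <- sheetSim(phaseJitterSD = 0.05, seed = 100 + s, Z = 5,
                    layerZ = 3)
    mean(illuminationPhaseSteps(sim$stack, zRange = 1)@stepSD)
  }, 0)
  expect_true(all(recovered > 0.025 & recovered < 0.1))
})
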
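test_that("bead fields have the requested flux, support empty fields, and are reproducible", {
  expect_identical(generateBeadField(16, 16, 3, nBeads = 0),
                   array(0, c(16, 16, 3)))
  ## single centred bead: Gaussian integral, boundary loss < 1%
  one <- generateBeadField(33, 33, 9, nBeads = 1, psfSigmaXY = 1.5,
                           psfSigmaZ = 1.2, flux = 1000, margin = 15,
                           layerZ = 5, seed = 3)
  expect_gt(sum(one), 0.99 * 1000)
  expect_lt(sum(one), 1.01 * 1000)
  expect_error(generateBeadField(8, 8, 3, psfSigmaXY = 0), "sigma")
  a <- generateBeadField(16, 16, 3, nBeads = 20, seed = 9)
  b <- generateBeadField(16, 16, 3, nBeads = 20, seed = 9)
  expect_identical(a, b)
})

test_that("unmodulated noise-free acquisitions have identical planes within each z", {
  sc <- simScenario(sizeX = 16, sizeY = 16, sizeZ = 3, modDepth = 0)
  dens <- generateBeadField(16, 16, 3, nBeads = 10, seed = 2)
  sim <- generateRawSIM(dens, sc)
  for (z in 1:3) {
    ref <- getPlane(sim$stack, p = 1, z = z, a = 1)
    for (a in 1:3) for (p in 1:5)
      expect_equal(getPlane(sim$stack, p = p, z = z, a = a), ref,
                   tolerance = 1e-12)
  }
})

test_that("full modulation shows (max-min)/(max+min) equal to m at pattern-aligned pixels", {
  sc <- simScenario(sizeX = 32, sizeY = 32, sizeZ = 1, modDepth = 1,
                    thetaDeg = c(15, 75, 135))
  dens <- array(100, c(32, 32, 1))   # uniform sample isolates the stripes
  sim <- generateRawSIM(dens, sc)
  ## phase-aligned pixels: cosine attains +1 for some phase where the
  ## carrier phase is a multiple of 2*pi/P
  ph <- stackData(sim$stack)[, , 1, , 1, 1, 1]
  mx <- apply(ph, c(1, 2), max); mn <- apply(ph, c(1, 2), min)
  vis <- (mx - mn) / (mx + mn)
  ## 5 equally spaced phases sample the cosine within 2*pi/10 of its
  ## extremes everywhere: visibility >= cos(pi/5)*m and <= m
  expect_lte(max(vis), 1 + 1e-9)
  expect_gte(min(vis), cos(pi / 5) - 1e-9)
  expect_gt(mean(vis > 0.995), 0.02)           # aligned pixels do reach m
})

test_that("bleaching follows its closed form along the acquisition order", {
  b <- 0.01
  sc <- simScenario(sizeX = 8, sizeY = 8, sizeZ = 3, modDepth = 0,
                    bleachFraction = b)
  dens <- array(50, c(8, 8, 3))
  sim <- generateRawSIM(dens, sc)
  mu <- apply(planeSequence(sim$stack), 3, mean)
  N <- length(mu)
  expect_equal(mu[N] / mu[1], (1 - b)^(N - 1), tolerance = 1e-9)
  ## per-plane expected means recorded in the truth match the stack
  expect_equal(as.vector(sim$truth$expectedMeans), mu, tolerance = 1e-9)
})

test_that("generators are deterministic under a fixed seed and noise-free stats hit closed forms", {
  sc <- simScenario(sizeX = 16, sizeY = 16, sizeZ = 3, modDepth = 0.7,
                    photonsPerUnit = 1, readNoiseSD = 2, seed = 21)
  dens <- generateBeadField(16, 16, 3, nBeads = 15, seed = 4)
  s1 <- generateRawSIM(dens, sc)
  s2 <- generateRawSIM(dens, sc)
  expect_identical(stackData(s1$stack), stackData(s2$stack))
  ## noise-free: per-angle gains appear exactly in plane means
  scg <- simScenario(sizeX = 16, sizeY = 16, sizeZ = 3, modDepth = 0,
                     angleGains = c(1, 1, 0.8))
  simg <- generateRawSIM(dens, scg)
  mu <- apply(stackData(simg$stack), 6, mean)
  expect_equal(mu[2] / mu[1], 1, tolerance = 1e-9)
  expect_equal(mu[3] / mu[1], 0.8, tolerance = 1e-9)
})

test_that("recon-like stacks honour their constructed tails and determinism", {
  rc0 <- generateReconLike(dim = c(10, 10, 5), noiseSD = 0, seed = 1)
  expect_gte(min(stackData(rc0)), 0)
  rc <- mmrOracleRecon()
  v <- stackData(rc)
  expect_identical(sum(v == 100), 100L)
  expect_identical(sum(v == -50), 100L)
  expect_lt(abs(median(v)), 1)                  # background mode near zero
  expect_identical(stackData(mmrOracleRecon()), v)
  expect_error(generateReconLike(dim = c(4, 4, 2), ringingAmp = -1), ">= 0")
  ## density mode: negative lobes appear one slice off the feature layer
  dens <- array(0, c(8, 8, 5)); dens[4, 4, 3] <- 100
  rr <- generateReconLike(density = dens, noiseSD = 0, ringingAmp = 0.3)
  expect_lt(min(stackData(rr)[, , 1, 2, 1]), 0)
  expect_lt(min(stackData(rr)[, , 1, 4, 1]), 0)
  expect_gte(max(stackData(rr)[, , 1, 3, 1]), 50)
})
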
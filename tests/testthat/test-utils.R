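test_that("pseudo-widefield preserves constants and doubles the grid", {
  raw <- constRaw(100, Y = 8, X = 8, Z = 2)
  pwf <- pseudoWidefield(raw)
  expect_identical(dim(stackData(pwf))[1:2], c(16L, 16L))
  expect_equal(range(stackData(pwf)), c(100, 100), tolerance = 1e-9)
  expect_equal(pixelSizeXY(pwf), pixelSizeXY(raw) / 2)
})

test_that("phase averaging cancels the stripes: striped and unmodulated stacks agree", {
  dens <- generateBeadField(32, 32, 3, nBeads = 25, seed = 14)
  sim1 <- generateRawSIM(dens, simScenario(sizeX = 32, sizeY = 32,
                                           sizeZ = 3, modDepth = 0.9))
  sim0 <- generateRawSIM(dens, simScenario(sizeX = 32, sizeY = 32,
                                           sizeZ = 3, modDepth = 0))
  p1 <- stackData(pseudoWidefield(sim1$stack))
  p0 <- stackData(pseudoWidefield(sim0$stack))
  expect_lt(max(abs(p1 - p0)) / max(p0), 1e-6)
})

test_that("simple-ratio normalization flattens bleached slice means", {
  sc <- simScenario(sizeX = 8, sizeY = 8, sizeZ = 5, modDepth = 0,
                    bleachFraction = 0.02)
  sim <- generateRawSIM(array(40, c(8, 8, 5)), sc)
  pwf <- pseudoWidefield(sim$stack, normalize = TRUE)
  mu <- apply(stackData(pwf)[, , 1, , 1], 3, mean)
  expect_lt(diff(range(mu)) / mean(mu), 1e-9)
})

test_that("pseudo-widefield treats channels independently", {
  arr <- array(0, c(8, 8, 2, 5, 2, 3, 1))
  set.seed(15)
  arr[, , 1, , , , ] <- runif(length(arr[, , 1, , , , ]), 10, 20)
  arr[, , 2, , , , ] <- runif(length(arr[, , 2, , , , ]), 50, 90)
  both <- pseudoWidefield(RawSIMStack(arr))
  ch2 <- pseudoWidefield(RawSIMStack(arr[, , 2, , , , , drop = FALSE]))
  expect_equal(stackData(both)[, , 2, , ], stackData(ch2)[, , 1, , ],
               tolerance = 1e-12)
})

test_that("threshold conversion maps the range onto 16 bits with the documented linear rule", {
  v <- array(c(0, 100, 200, rep(0, 97)), c(10, 10, 1))
  rec <- ReconStack(v)
  out <- threshold16bit(rec, threshold = 0)
  expect_identical(max(out), 65535L)
  expect_identical(min(out), 0L)
  expect_identical(out[2, 1, 1, 1, 1], 32768L)   # round(65535 * 100/200)
  ## one voxel above threshold
  v2 <- array(0, c(5, 5, 1)); v2[3, 3, 1] <- 7
  out2 <- threshold16bit(ReconStack(v2), threshold = 0)
  expect_identical(sort(unique(as.vector(out2))), c(0L, 65535L))
  expect_error(threshold16bit(ReconStack(array(1, c(4, 4, 1))),
                              threshold = 5), "range")
})

test_that("threshold conversion is monotone and auto mode zeroes the below-mode fraction", {
  set.seed(16)
  v <- array(rnorm(4000, 0, 10), c(20, 20, 10))
  v[sample(4000, 50)] <- 200                     # features
  rec <- ReconStack(v)
  out <- threshold16bit(rec, threshold = "auto")
  ord <- order(as.vector(v))
  expect_true(all(diff(as.vector(out)[ord]) >= 0))
  m <- simqc:::stackMode(v)
  expect_true(all(out[v <= m] == 0L))            # everything below mode clipped
  expect_lt(abs(mean(out == 0L) - mean(v <= m)), 1e-3)
  expect_equal(attr(out, "thresholds"), m)
})

test_that("the stack FFT satisfies Parseval and point symmetry, and locates cosine gratings", {
  set.seed(17)
  f <- matrix(runif(32 * 32), 32)
  spec <- stackFFT(f, windowPct = 0, scaling = "none")
  n <- attr(spec, "padSize")
  expect_equal(sum(spec^2) / n^2, sum(f^2), tolerance = 1e-9)
  ## point symmetry about the DC-centred origin
  amp <- spec[, , 1]
  cx <- n / 2 + 1
  err <- 0
  for (a in 2:n) for (b in 2:n)
    err <- max(err, abs(amp[a, b] - amp[2 * cx - a, 2 * cx - b]))
  expect_lt(err, 1e-9)
  ## centred impulse: constant amplitude
  imp <- matrix(0, 16, 16); imp[9, 9] <- 3
  spImp <- stackFFT(imp, windowPct = 0, scaling = "none")
  expect_lt(diff(range(spImp)), 1e-9)
  ## cosine grating at k cycles/pixel: symmetric peak pair in padded bins
  k <- 4 / 32
  g <- matrix(cos(2 * pi * k * (col(matrix(0, 32, 32)) - 1)), 32)
  spG <- stackFFT(g, windowPct = 0, scaling = "none")[, , 1]
  pk <- arrayInd(order(spG, decreasing = TRUE)[1:2], dim(spG))
  expect_setequal((pk[, 2] - cx) / n, c(k, -k))
  expect_true(all(pk[, 1] == cx))
})

test_that("windowed transforms keep the window inside bounds", {
  expect_error(stackFFT(matrix(0, 4, 4), windowPct = 60), "windowPct")
  w <- simqc:::gaussianEdgeWindow(50, 50, 6)
  expect_equal(max(w), 1)
  expect_lt(w[1, 25], 0.05)                      # edge strongly tapered
  expect_equal(w[25, 25], 1)                     # interior untouched
})
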
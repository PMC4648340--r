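test_that("the Anscombe transform matches its closed form and stabilizes Poisson variance", {
  expect_equal(anscombe(0), 2 * sqrt(3 / 8), tolerance = 1e-12)
  expect_equal(anscombe(1), 2 * sqrt(11 / 8), tolerance = 1e-12)
  expect_error(anscombe(-0.1), "non-negative")
  set.seed(101)
  x <- rpois(1e5, 100)
  expect_equal(var(anscombe(x)), 1, tolerance = 0.1)
})

test_that("phase order indices land where a brute-force DFT argmax puts them", {
  ## printed example: 5 phases x 3 z-sections
  idx <- phaseOrderIndices(5, 1)
  expect_identical(c(idx$L, idx$idx1, idx$idx2), c(15L, 4L, 7L))
  expect_identical(unlist(phaseOrderIndices(5, 0)[c("idx1", "idx2")],
                          use.names = FALSE), c(2L, 3L))
  expect_identical(phaseOrderIndices(3, 1)$idx1, 4L)
  expect_true(is.na(phaseOrderIndices(3, 1)$idx2))
  ## brute force: single-order synthetic phase series
  for (P in c(3, 5, 7)) for (zw in 0:2) {
    L <- P * (2 * zw + 1)
    for (O in 1:2) {
      if (O == 2 && P < 5) next
      j <- 0:(L - 1)
      series <- cos(2 * pi * O * (j %% P) / P + 0.3)
      mag <- Mod(fft(series))
      half <- 2:(floor(L / 2) + 1)
      bruteIdx <- half[which.max(mag[half])]
      expected <- if (O == 1) phaseOrderIndices(P, zw)$idx1
        else phaseOrderIndices(P, zw)$idx2
      expect_identical(bruteIdx, as.integer(expected))
    }
  }
})

test_that("the Wiener suggestion follows w = 0.17 / MCNR^2 and decreases monotonically", {
  expect_identical(wienerSuggestion(1), 0.17)
  expect_identical(wienerSuggestion(2), 0.0425)
  w <- wienerSuggestion(c(1, 2, 4, 8, 16))
  expect_true(all(diff(w) < 0))
  expect_identical(wienerSuggestion(Inf), 0)
  expect_warning(out <- wienerSuggestion(0), "undefined")
  expect_true(is.na(out))
})

test_that("constant phase series put all power at DC: zero modulation amplitude", {
  raw <- constRaw(50, Y = 6, X = 6, Z = 3)
  expect_warning(res <- mcnr(raw), "noise-free")
  expect_true(all(res@map == 0))
})

test_that("feature-mean MCNR sits at the analytic noise floor without modulation and rises with it", {
  ## pure noise: E[sqrt(A1^2+A2^2)] / sd(|F_noise|) for complex Gaussian
  ## components is scale-free, ~2.9; modulated scenarios must exceed it
  floorVals <- vapply(1:3, function(s)
    mcnr(noisyBeadSim(m = 0, seed = s)$stack)@featureMeanMcnr, 0)
  expect_true(all(floorVals > 1.5 & floorVals < 4.5))
  m02 <- mcnr(noisyBeadSim(m = 0.2, seed = 1)$stack)@featureMeanMcnr
  expect_gt(m02, max(floorVals) * 0.9)
  m09 <- mcnr(noisyBeadSim(m = 0.9, seed = 1)$stack)@featureMeanMcnr
  expect_gt(m09, m02)
})

test_that("the MCNR map drifts less than 5% under a 10x digital gain", {
  sim <- noisyBeadSim(m = 0.6, seed = 13, flux = 5000)   # lambda >= 50 on features
  raw <- sim$stack
  r1 <- mcnr(raw)
  r10 <- mcnr(RawSIMStack(stackData(raw) * 10, bitDepth = 32))
  sel <- r1@map > r1@otsuCut                    # compare over features
  drift <- abs(r10@map[sel] - r1@map[sel]) / r1@map[sel]
  expect_lt(mean(drift), 0.05)
  expect_lt(abs(r10@featureMeanMcnr - r1@featureMeanMcnr) /
              r1@featureMeanMcnr, 0.05)
})

test_that("mcnr results carry consistent Wiener suggestions and z-window bookkeeping", {
  res <- mcnr(noisyBeadSim(m = 0.5, seed = 2)$stack, zw = 1)
  expect_identical(res@zWindow, 1L)
  expect_equal(res@wienerSuggestion, 0.17 / res@featureMeanMcnr^2,
               tolerance = 1e-12)
  expect_true(all(res@map >= 0))
  expect_identical(dim(res@map)[1:2], c(32L, 32L))
})
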
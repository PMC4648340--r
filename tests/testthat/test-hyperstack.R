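test_that("reorderToCPZAT handles identity, a hand-enumerated permutation, and round trips", {
  ## identity: source already canonical
  pl <- array(as.numeric(seq_len(2 * 2 * 6)), c(2, 2, 6))
  s <- reorderToCPZAT(pl, "CPZAT", c(C = 2, P = 3, Z = 1, A = 1, T = 1))
  expect_identical(planeSequence(s), pl * 1.0)

  ## hand-enumerated 4-plane case: ZPCAT source, z fastest then p
  pl4 <- array(as.numeric(rep(0:3, each = 4)), c(2, 2, 4))
  s4 <- reorderToCPZAT(pl4, "ZPCAT", c(C = 1, P = 2, Z = 2, A = 1, T = 1))
  expect_equal(planeSequence(s4)[1, 1, ], c(0, 2, 1, 3))

  ## round trip: store canonical planes under PCZAT, reorder back
  set.seed(1)
  dims <- c(C = 2, P = 3, Z = 2, A = 2, T = 1)
  x <- array(as.numeric(sample(0:100, 4 * prod(dims), TRUE)),
             c(2, 2, prod(dims)))
  stored <- storeInOrder(x, "PCZAT", dims)
  expect_equal(planeSequence(reorderToCPZAT(stored, "PCZAT", dims)), x)
})

test_that("reorderToCPZAT inverts every one of the 120 orderings and preserves intensity sums", {
  dims <- c(C = 2, P = 3, Z = 2, A = 2, T = 2)
  n <- prod(dims)
  labels <- array(as.numeric(rep(seq_len(n), each = 4)), c(2, 2, n))
  perms <- allOrderStrings()
  expect_length(perms, 120L)
  bad <- 0L
  for (ord in perms) {
    stored <- storeInOrder(labels, ord, dims)   # independent forward map
    back <- reorderToCPZAT(stored, ord, dims)
    if (!identical(planeSequence(back), labels)) bad <- bad + 1L
    if (sum(stackData(back)) != sum(labels)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("reorder and RawSIMStack reject inconsistent plane counts and bad orders", {
  pl <- array(0, c(2, 2, 7))
  expect_error(reorderToCPZAT(pl, "CPZAT",
                              c(C = 1, P = 5, Z = 27, A = 1, T = 1)),
               "does not match")
  expect_error(reorderToCPZAT(pl, "QPZAT",
                              c(C = 1, P = 7, Z = 1, A = 1, T = 1)),
               "C, P, Z, A, T")
  expect_error(RawSIMStack(array(-1, c(2, 2, 1, 3, 1, 1, 1))),
               ">= 0")
})

test_that("cropping applies identical physical bounds to raw and recon, doubling recon xy", {
  raw <- constRaw(7, Y = 64, X = 64, P = 2, Z = 4, A = 1)
  full <- cropRegion(0, 64, 0, 64, 0, 4)
  expect_identical(stackData(cropStack(raw, full)), stackData(raw))

  rec <- ReconStack(array(rnorm(128 * 128 * 4), c(128, 128, 4)))
  reg <- cropRegion(16, 48, 8, 40, 1, 3)
  rawC <- cropStack(raw, reg)
  recC <- cropStack(rec, reg)
  expect_identical(dim(stackData(rawC))[1:2], c(32L, 32L))
  expect_identical(dim(stackData(recC))[1:2], c(64L, 64L))
  expect_identical(dim(stackData(rawC))[5], 2L)
  ## recon x in [32, 96), z half-open [1, 3) -> original slices 2:3
  expect_identical(stackData(recC)[, , 1, 1, 1],
                   stackData(rec)[17:80, 33:96, 1, 2, 1])

  expect_error(cropRegion(0, 10, 0, 10, 2, 2), "non-empty")
  expect_error(cropStack(raw, cropRegion(0, 65, 0, 64, 0, 4)), "bounds")
})

test_that("accessors and show methods report the stack geometry", {
  s <- constRaw(1, Y = 4, X = 6, C = 2, P = 3, Z = 2, A = 3, T = 1,
                bitDepth = 15)
  expect_identical(c(nChannels(s), nPhases(s), nZSlices(s), nAngles(s),
                     nTimepoints(s)), c(2L, 3L, 2L, 3L, 1L))
  expect_identical(bitDepth(s), 15)
  expect_output(show(s), "C=2 P=3 Z=2 A=3")
  r <- ReconStack(array(0, c(4, 4, 2)), fullRange = FALSE)
  expect_false(fullRange(r))
  expect_output(show(r), "clipped")
})
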
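test_that("16-bit raw stacks round trip losslessly with sidecar metadata", {
  set.seed(11)
  arr <- array(sample(0:32767, 8 * 8 * 2 * 3 * 2, TRUE),
               c(8, 8, 2, 3, 2, 1, 1))
  raw <- RawSIMStack(arr, bitDepth = 15, pixelXY = 0.08, pixelZ = 0.125)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeStackTIFF(raw, tf)
  back <- readRawStackTIFF(tf)
  expect_equal(stackData(back), stackData(raw) * 1.0)
  expect_equal(bitDepth(back), 15)
  expect_equal(pixelSizeXY(back), 0.08)
  expect_equal(sum(stackData(back)), sum(arr))
})

test_that("full-range float recon stacks (negative values) round trip to float32 precision", {
  set.seed(12)
  rec <- ReconStack(array(rnorm(16 * 16 * 4) * 100, c(16, 16, 4)),
                    pixelXY = 0.04, fullRange = TRUE)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeStackTIFF(rec, tf)
  back <- readReconStackTIFF(tf)
  ## float32 storage: one quantization, then exact
  expect_lt(max(abs(stackData(back) - stackData(rec))),
            1e-4 * max(abs(stackData(rec))))
  writeStackTIFF(back, tf)
  again <- readReconStackTIFF(tf)
  expect_identical(stackData(again), stackData(back))
  expect_true(fullRange(back))
  expect_true(min(stackData(back)) < 0)
})

test_that("page count inconsistent with declared dimensions is a dimension error", {
  planes <- lapply(1:7, function(i) matrix(runif(16), 4))
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(planes, tf, bits.per.sample = 16L, compression = "none")
  expect_error(
    readRawStackTIFF(tf, config = list(C = 1, P = 5, Z = 27, A = 1, T = 1,
                                       pixel_xy = 0.08, pixel_z = 0.125)),
    "does not match")
})

test_that("built-in codec agrees with the tiff package on common ground", {
  ## our reader on a tiff-package-written 16-bit file
  set.seed(13)
  xi <- matrix(sample(0:65535, 64), 8)
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(xi / 65535), tf, bits.per.sample = 16L,
                  compression = "none")
  expect_identical(simqc:::readTiffPlanes(tf)[[1]], xi * 1.0)
  ## the tiff package on our float file (in-range values)
  x <- matrix(runif(64), 8)
  simqc:::writeFloatTiff(list(x), tf)
  expect_lt(max(abs(tiff::readTIFF(tf, all = TRUE)[[1]] - x)), 1e-6)
})

test_that("non-canonical plane order declared in the sidecar is reordered on read", {
  dims <- c(C = 1, P = 2, Z = 2, A = 1, T = 1)
  canonical <- array(rep(c(10, 20, 30, 40), each = 4), c(2, 2, 4))
  stored <- storeInOrder(canonical, "ZPCAT", dims)
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(i) stored[, , i] / 65535), tf,
                  bits.per.sample = 16L, compression = "none")
  cfg <- c(list(order = "ZPCAT", pixel_xy = 0.08, pixel_z = 0.125),
           as.list(dims))
  back <- readRawStackTIFF(tf, config = cfg)
  expect_equal(planeSequence(back), canonical)
})

test_that("dimension-order presets are exposed and editable JSON", {
  p <- dimensionOrderPresets()
  expect_identical(p$omx, "CPZAT")
  expect_true(all(c("zeiss", "nikon") %in% names(p)))
})
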
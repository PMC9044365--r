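test_that("makePhantom produces clipped, reproducible ellipse images", {
  spec1 <- phantomSpec(size = c(64L, 64L), nEllipses = 1L, seed = 3L)
  img <- makePhantom(spec1)
  expect_gt(img[32, 32], 0)           # center inside the outline ellipse
  expect_identical(img[1, 1], 0)      # corners outside
  expect_identical(img[64, 64], 0)

  spec <- phantomSpec(size = c(64L, 64L), seed = 10L)
  expect_identical(makePhantom(spec), makePhantom(spec))
  spec2 <- phantomSpec(size = c(64L, 64L), seed = 11L)
  expect_false(identical(makePhantom(spec), makePhantom(spec2)))

  expect_true(all(img >= 0 & img <= 1))
  speckled <- makePhantom(phantomSpec(size = c(64L, 64L),
                                      contrast = "pdfs_like",
                                      speckleSd = 0.3, seed = 10L))
  expect_true(all(speckled >= 0 & speckled <= 1))
  expect_false(identical(speckled, makePhantom(spec)))
})

test_that("coil sensitivities are normalized with distinct peaks", {
  one <- makeCoilSensitivities(1, c(32, 32), seed = 1)
  expect_lt(max(abs(Mod(sensMaps(one)[, , 1]) - 1)), 1e-10)

  s <- makeCoilSensitivities(15, c(64, 64), seed = 2)
  ssq <- apply(Mod(sensMaps(s))^2, c(1, 2), sum)
  expect_lt(max(abs(ssq - 1)), 1e-6)

  peaks <- apply(sensMaps(s), 3, function(m) which.max(Mod(m)))
  expect_identical(anyDuplicated(peaks), 0L)

  expect_error(makeCoilSensitivities(0, c(32, 32)), "nCoils")
})

test_that("simulateDataset is lossless when unaccelerated and reproducible", {
  spec <- phantomSpec(size = c(32L, 32L))
  data1 <- simulateDataset(3, spec, nCoils = 4, accel = 1, noiseSd = 0,
                           seed = 5)
  for (s in data1) {
    zf <- zeroFilledRecon(s@kspace, s@mask, target = dim(groundTruth(s)))
    expect_lt(max(abs(zf - groundTruth(s))), 1e-6)
  }

  data4 <- simulateDataset(10, spec, nCoils = 4, accel = 4, noiseSd = 0,
                           seed = 5)
  for (s in data4)
    expect_identical(sum(maskVector(s@mask)), as.integer(round(32 / 4)))

  again <- simulateDataset(10, spec, nCoils = 4, accel = 4, noiseSd = 0,
                           seed = 5)
  expect_identical(lapply(data4, groundTruth), lapply(again, groundTruth))
  expect_identical(lapply(data4, function(s) kspaceData(s@kspace)),
                   lapply(again, function(s) kspaceData(s@kspace)))
})

test_that("zero-filled NMSE grows with acceleration", {
  spec <- phantomSpec(size = c(64L, 64L))
  meanNmse <- vapply(c(1L, 2L, 4L, 8L), function(acc) {
    data <- simulateDataset(4, spec, nCoils = 8, accel = acc, noiseSd = 0,
                            seed = 31)
    mean(vapply(data, function(s)
      nmse(groundTruth(s),
           zeroFilledRecon(s@kspace, s@mask, target = dim(groundTruth(s)))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanNmse) >= 0))
  expect_lt(meanNmse[1], 1e-10)
})
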
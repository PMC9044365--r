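test_that("fft2c matches the brute-force centered DFT and its closed forms", {
  x <- randomComplexMatrix(4, seed = 11)
  expect_lt(max(Mod(fft2c(x) - dft2cOracle(x))), 1e-10)

  expect_equal(fft2c(matrix(0, 4, 4)), matrix(0i, 4, 4))

  k <- fft2c(matrix(2.5, 4, 4))
  expect_equal(k[3, 3], 2.5 * 4 + 0i, tolerance = 1e-12)  # DC = c * N
  k[3, 3] <- 0
  expect_lt(max(Mod(k)), 1e-12)

  expect_error(fft2c(1:8), "2-D")
})

test_that("ifft2c inverts fft2c and conserves energy", {
  x <- randomComplexMatrix(8, seed = 2)
  expect_lt(max(Mod(ifft2c(fft2c(x)) - x)), 1e-10)

  k <- fft2c(x)
  expect_lt(abs(sum(Mod(x)^2) - sum(Mod(k)^2)) / sum(Mod(x)^2), 1e-8)

  imp <- matrix(0i, 4, 4); imp[3, 3] <- 1  # unit impulse at the DC position
  expect_lt(max(Mod(ifft2c(imp) - matrix(1 / 4, 4, 4))), 1e-12)
})

test_that("round trip and Parseval hold for a range of sizes", {
  for (n in c(6, 16, 33, 64)) {
    x <- randomComplexMatrix(n, seed = n)
    expect_lt(max(Mod(ifft2c(fft2c(x)) - x)), 1e-10)
    expect_lt(abs(sum(Mod(x)^2) - sum(Mod(fft2c(x))^2)) / sum(Mod(x)^2), 1e-8)
  }
})

test_that("rssCombine implements the root-sum-of-squares identity", {
  one <- array(randomComplexMatrix(5, seed = 3), dim = c(5, 5, 1))
  expect_equal(rssCombine(one), Mod(one[, , 1]))

  two <- array(0i, dim = c(1, 1, 2))
  two[1, 1, 1] <- 3; two[1, 1, 2] <- 4i
  expect_equal(rssCombine(two)[1, 1], 5)

  set.seed(4)
  many <- array(complex(real = rnorm(8 * 8 * 15), imaginary = rnorm(8 * 8 * 15)),
                dim = c(8, 8, 15))
  expect_lt(max(abs(rssCombine(many) - rssOracle(many))), 1e-12)

  # invariant to a global per-coil phase rotation
  rot <- many
  rot[, , 7] <- rot[, , 7] * exp(1.234i)
  expect_lt(max(abs(rssCombine(rot) - rssCombine(many))), 1e-12)

  expect_error(rssCombine(array(0i, dim = c(4, 4, 0))), "coil")
})

test_that("applySensitivities realizes the coil-model forward operator", {
  x <- makePhantom(phantomSpec(size = c(32L, 32L), seed = 8L))

  ident <- new("CoilSensitivitySet",
               maps = array(1 + 0i, dim = c(32, 32, 1)), normalized = TRUE)
  ks <- applySensitivities(x, ident, noiseSd = 0)
  expect_equal(kspaceData(ks)[, , 1, 1], fft2c(x), tolerance = 1e-12)

  sens <- makeCoilSensitivities(4, c(32, 32), seed = 5)
  ks4 <- applySensitivities(x, sens, noiseSd = 0)
  imgs <- array(0i, dim = c(32, 32, 4))
  for (i in 1:4) imgs[, , i] <- ifft2c(kspaceData(ks4)[, , i, 1])
  expect_lt(max(abs(rssCombine(imgs) - abs(x))), 1e-6)

  a <- applySensitivities(x, sens, noiseSd = 0.1, seed = 42)
  b <- applySensitivities(x, sens, noiseSd = 0.1, seed = 42)
  c <- applySensitivities(x, sens, noiseSd = 0.1, seed = 43)
  expect_identical(kspaceData(a), kspaceData(b))
  expect_false(identical(kspaceData(a), kspaceData(c)))

  expect_error(applySensitivities(x[1:16, ], sens), "spatial shape")
})

test_that("makeMask meets the exact-count and center-block contracts", {
  m <- makeMask(320, 4, 0.08, kind = "random", seed = 7)
  v <- maskVector(m)
  expect_identical(sum(v), 80L)
  center <- 148:173  # 26 consecutive central columns
  expect_true(all(v[center] == 1L))

  for (kind in c("random", "equispaced"))
    expect_identical(sum(maskVector(makeMask(320, 1, kind = kind, seed = 9))),
                     320L)

  eq <- makeMask(16, 4, 0, kind = "equispaced", seed = 0)
  expect_identical(which(maskVector(eq) == 1L), c(1L, 5L, 9L, 13L))

  # exact ones count across a (columns, acceleration) grid
  for (cols in c(64L, 100L, 320L, 368L))
    for (acc in c(2L, 4L, 8L))
      expect_identical(sum(maskVector(makeMask(cols, acc, seed = cols + acc))),
                       as.integer(round(cols / acc)))

  expect_error(makeMask(320, 8, centerFraction = 0.5), "budget")
})

test_that("applyMask zeroes exactly the unsampled columns", {
  sens <- makeCoilSensitivities(3, c(32, 32), seed = 1)
  ks <- applySensitivities(makePhantom(phantomSpec(size = c(32L, 32L))),
                           sens, noiseSd = 0)

  allOnes <- makeMask(32, 1)
  expect_identical(kspaceData(applyMask(ks, allOnes)), kspaceData(ks))

  m <- makeMask(32, 4, kind = "random", seed = 3)
  masked <- applyMask(ks, m)
  v <- maskVector(m)
  expect_true(all(kspaceData(masked)[, v == 0L, , ] == 0))
  expect_identical(kspaceData(masked)[, v == 1L, , ],
                   kspaceData(ks)[, v == 1L, , ])

  # per-column energy bookkeeping
  colEnergy <- apply(Mod(kspaceData(ks))^2, 2, sum)
  expect_equal(sum(Mod(kspaceData(masked))^2), sum(colEnergy[v == 1L]),
               tolerance = 1e-12)

  # idempotence
  expect_identical(kspaceData(applyMask(masked, m)), kspaceData(masked))

  expect_error(applyMask(ks, makeMask(64, 4, seed = 1)), "column")
})

test_that("centerCrop uses floor margins with trailing-side drop", {
  big <- matrix(seq_len(640 * 368), 640, 368)
  crop <- centerCrop(big, c(320, 320))
  expect_identical(crop, big[161:480, 25:344])

  x <- matrix(rnorm(25), 5, 5)
  expect_identical(centerCrop(x, c(5, 5)), x)
  expect_identical(centerCrop(x, c(4, 4)), x[1:4, 1:4])
  expect_error(centerCrop(x, c(6, 5)), "exceeds")
})

test_that("zeroFilledRecon is lossless when fully sampled and aliased when not", {
  spec <- phantomSpec(size = c(64L, 64L), seed = 21L)
  gt <- makePhantom(spec)
  sens <- makeCoilSensitivities(8, c(64, 64), seed = 22)
  ks <- applySensitivities(gt, sens, noiseSd = 0)

  full <- zeroFilledRecon(ks, makeMask(64, 1))
  expect_lt(max(abs(full - gt)), 1e-6)

  aliased <- zeroFilledRecon(ks, makeMask(64, 4, kind = "random", seed = 2))
  expect_gt(nmse(gt, aliased), 0)

  again <- zeroFilledRecon(ks, makeMask(64, 4, kind = "random", seed = 2))
  expect_identical(aliased, again)
})
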
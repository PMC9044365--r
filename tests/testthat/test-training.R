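test_that("l1Loss is the symmetric mean absolute difference", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(l1Loss(a, a), 0)
  expect_equal(l1Loss(matrix(0.5, 8, 8), matrix(0, 8, 8)), 0.5)
  b <- matrix(runif(64), 8, 8)
  expect_identical(l1Loss(a, b), l1Loss(b, a))
  expect_error(l1Loss(a, matrix(0, 4, 4)), "shape")
})

test_that("nmse matches its defining ratio and scale invariance", {
  set.seed(1)
  gt <- matrix(rnorm(100), 10, 10)
  pred <- matrix(rnorm(100), 10, 10)
  expect_identical(nmse(gt, gt), 0)
  expect_equal(nmse(gt, matrix(0, 10, 10)), 1)
  expect_equal(nmse(gt, pred), sum((gt - pred)^2) / sum(gt^2),
               tolerance = 1e-12)
  expect_equal(nmse(3.7 * gt, 3.7 * pred), nmse(gt, pred), tolerance = 1e-12)
  expect_error(nmse(matrix(0, 4, 4), pred[1:4, 1:4]), "zero")
})

test_that("psnr obeys its closed forms and monotonicity", {
  gt <- matrix(0, 10, 10)
  pred <- matrix(0.1, 10, 10)  # MSE = 0.01
  expect_equal(psnr(gt, pred, dataRange = 1), 20)
  expect_equal(psnr(gt, pred, dataRange = 2) - psnr(gt, pred, dataRange = 1),
               20 * log10(2), tolerance = 1e-12)
  expect_identical(psnr(pred, pred), Inf)

  # strictly decreasing in MSE at fixed range
  p <- vapply(c(0.05, 0.1, 0.2, 0.4), function(s)
    psnr(gt, matrix(s, 10, 10), dataRange = 1), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("ssim agrees with the window-loop oracle and a reference value", {
  gt <- makePhantom(phantomSpec(seed = 5L))
  shifted <- gt + 0.1
  s <- ssim(gt, shifted, dataRange = max(gt))
  expect_lt(s, 1)
  # frozen cross-check against scikit-image structural_similarity
  # (win_size = 7, data_range = max(gt)) on this seeded phantom pair
  expect_equal(s, 0.4899253075, tolerance = 1e-6)
  expect_equal(s, ssimOracle(gt, shifted, max(gt)), tolerance = 1e-10)

  expect_identical(ssim(gt, gt), 1)

  set.seed(2)
  for (k in 1:3) {
    a <- matrix(runif(15 * 15), 15, 15)
    b <- matrix(runif(15 * 15), 15, 15)
    v <- ssim(a, b, dataRange = 1)
    expect_gte(v, -1); expect_lte(v, 1)
  }
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5), dataRange = 1),
               "window")
})

test_that("training reduces the loss and honours the seeding contract", {
  spec <- phantomSpec(size = c(32L, 32L))
  data <- simulateDataset(6, spec, nCoils = 4, accel = 4, noiseSd = 0,
                          seed = 17)
  cfg <- tinyConfig()
  model <- buildMLPED(cfg, seed = 2)

  frozen <- trainMLPED(model, data, trainConfig(epochs = 2, learningRate = 0,
                                                seed = 4))
  expect_identical(frozen$model@params, model@params)
  expect_equal(frozen$history[1], frozen$history[2], tolerance = 1e-12)

  fit1 <- trainMLPED(model, data, trainConfig(epochs = 4, seed = 4))
  expect_lt(fit1$history[4], fit1$history[1])
  fit2 <- trainMLPED(model, data, trainConfig(epochs = 4, seed = 4))
  expect_identical(fit1$history, fit2$history)

  expect_error(trainMLPED(model, list(), trainConfig(epochs = 1)), "empty")
})

test_that("evaluation reports per-volume metrics with exact optima on gt", {
  gt <- makePhantom(phantomSpec(seed = 8L))
  rep <- metricReport(gt, gt)
  expect_identical(rep$nmse, 0)
  expect_identical(rep$ssim, 1)
  expect_identical(rep$psnr, Inf)

  spec <- phantomSpec(size = c(32L, 32L))
  data <- simulateDataset(3, spec, nCoils = 4, accel = 4, noiseSd = 0,
                          seed = 23)
  model <- setMode(buildMLPED(tinyConfig(), seed = 2), "eval")
  report <- evaluateModel(model, data)
  expect_identical(nrow(report), 3L)
  expect_named(report, c("volume", "nmse", "psnr", "ssim"))

  zf <- evaluateModel(model, data, reconstruction = "zero_filled")
  expect_identical(nrow(zf), 3L)
  expect_true(all(zf$nmse > 0))

  tmp <- tempfile(fileext = ".tsv")
  writeMetricsTable(report, tmp)
  back <- read.delim(tmp)
  expect_equal(back$nmse, report$nmse, tolerance = 1e-12)
})
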
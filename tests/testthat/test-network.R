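test_that("encoder blocks preserve shape and match parameter arithmetic", {
  blk <- buildEncoderBlock(1, 32, seed = 1)
  x <- array(rnorm(16 * 16), dim = c(16, 16, 1))
  y <- blk$forward(x)
  expect_identical(dim(y), c(16L, 16L, 32L))

  expect_identical(countTrainableParameters(blk), as.integer(encBlockParamCount(1, 32)))
  expect_identical(as.integer(encBlockParamCount(1, 32)), 9696L)

  # dropout 0: train and eval forward agree
  expect_equal(blk$forward(x, training = TRUE), blk$forward(x))
})

test_that("compiled convolution agrees with the direct-sum oracle", {
  set.seed(7)
  x <- array(rnorm(10 * 10 * 3), dim = c(10, 10, 3))
  w <- array(rnorm(3 * 3 * 3 * 5), dim = c(3, 3, 3, 5))
  b <- rnorm(5)
  tp <- mlped:::agTape()
  y <- mlped:::agConv2d(tp, mlped:::agLeaf(tp, x), mlped:::agLeaf(tp, w),
                        mlped:::agLeaf(tp, b))
  expect_lt(max(abs(y$value - convOracle(x, w, b))), 1e-10)
})

test_that("rmp appends one pooled channel per kernel behind the input", {
  set.seed(1)
  x <- array(rnorm(32 * 32 * 32), dim = c(32, 32, 32))
  y <- rmp(x, kernels = c(2, 3, 5, 6), seed = 2)
  expect_identical(dim(y), c(32L, 32L, 36L))
  expect_identical(y[, , 1:32], x)  # residual pass-through

  # zero 1x1 weights: appended channels are the broadcast biases
  params <- list()
  for (j in 1:4) {
    params[[paste0("p", j, ".w")]] <- array(0, dim = c(1, 1, 32, 1))
    params[[paste0("p", j, ".b")]] <- j / 10
  }
  yz <- rmp(x, kernels = c(2, 3, 5, 6), params = params)
  for (j in 1:4)
    expect_lt(max(abs(yz[, , 32 + j] - j / 10)), 1e-12)

  # constant input: pooled branch = w * c + b regardless of the window
  xc <- array(2, dim = c(12, 12, 2))
  params <- list(p1.w = array(c(0.5, -0.25), dim = c(1, 1, 2, 1)), p1.b = 0.1)
  yc <- rmp(xc, kernels = 3, params = params)
  expect_lt(max(abs(yc[, , 3] - (2 * 0.5 + 2 * -0.25 + 0.1))), 1e-12)

  # compiled max pooling itself against the loop oracle
  set.seed(3)
  xm <- array(rnorm(12 * 12 * 2), dim = c(12, 12, 2))
  expect_equal(mlped:::.maxpool_fwd(xm, 3L)$out, maxpoolOracle(xm, 3))

  expect_error(rmp(array(0, dim = c(4, 4, 1)), kernels = c(2, 6)), "kernel")
})

test_that("zoomInOut preserves shape and enforces divisibility", {
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  expect_identical(dim(zoomInOut(x, 2, seed = 1)), c(16L, 16L, 8L))
  expect_identical(dim(zoomInOut(x, 4, seed = 1)), c(16L, 16L, 8L))
  bad <- array(rnorm(15 * 15 * 4), dim = c(15, 15, 4))
  expect_error(zoomInOut(bad, 2), "divisible")
})

test_that("mlpModule is shape-preserving with a residual identity at zero", {
  cfg <- networkConfig(firstChannels = 8)
  x <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  y <- mlpModule(x, cfg, seed = 4)
  expect_identical(dim(y), dim(x))

  params <- withr::with_seed(4, mlped:::mlpParams(8L, cfg))
  zero <- lapply(params, function(p) p * 0)
  expect_equal(mlpModule(x, cfg, params = zero), x)

  # closed-form parameter arithmetic for the 32-channel level-1 module
  cfg32 <- networkConfig()
  p32 <- withr::with_seed(1, mlped:::mlpParams(32L, cfg32))
  wide <- 32 + 4
  expected <- 4 * (32 + 1) +                     # 1x1 reductions
    3 * convParams(3, 3, wide, wide) +           # zoom-in/zoom-out convs
    convParams(3, 3, wide, 32)                   # projection
  expect_identical(sum(vapply(p32, length, integer(1))), as.integer(expected))
})

test_that("pixelShuffle is the standard bijective sub-pixel rearrangement", {
  x <- array(rnorm(6 * 5 * 9), dim = c(6, 5, 9))
  expect_identical(pixelShuffle(x, 1), x)

  v <- array(as.numeric(1:4), dim = c(1, 1, 4))
  expect_identical(pixelShuffle(v, 2)[, , 1],
                   matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))

  set.seed(5)
  t8 <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
  y <- pixelShuffle(t8, 2)
  expect_identical(dim(y), c(8L, 8L, 2L))
  expect_identical(sort(as.numeric(y)), sort(as.numeric(t8)))
  expect_identical(mlped:::pixelUnshuffleArray(y, 2L), t8)

  expect_error(pixelShuffle(array(0, dim = c(2, 2, 6)), 2), "divisible")
})

test_that("decoder blocks double the spatial size into the level width", {
  cfg <- networkConfig(firstChannels = 8)
  dec <- buildDecoderBlock(16, 8, cfg, seed = 2)
  below <- array(rnorm(8 * 8 * 16), dim = c(8, 8, 16))
  skip <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  y <- dec$forward(below, skip)
  expect_identical(dim(y), c(16L, 16L, 8L))

  expect_identical(countTrainableParameters(dec),
                   as.integer(convParams(3, 3, 4, 8) +
                              encBlockParamCount(16, 8)))
  expect_error(buildDecoderBlock(6, 4, cfg), "divisible")
})

test_that("the assembled network meets its shape and determinism contracts", {
  cfg <- networkConfig(firstChannels = 8)
  model <- buildMLPED(cfg, seed = 1)
  for (n in c(64L, 80L)) {
    x <- matrix(runif(n * n), n, n)
    expect_identical(dim(mlpedForward(model, x)), c(n, n))
  }
  expect_error(mlpedForward(model, matrix(0, 100, 100)), "divisible")

  x <- matrix(runif(64 * 64), 64, 64)
  ev <- setMode(model, "eval")
  expect_identical(mlpedForward(ev, x), mlpedForward(ev, x))

  # parameter count is independent of the input size (fully convolutional)
  expect_identical(countTrainableParameters(model),
                   countTrainableParameters(buildMLPED(cfg, seed = 9)))
})

test_that("parameter counting matches closed forms at every scale", {
  expect_identical(countTrainableParameters(list()), 0L)
  single <- list(w = array(0, dim = c(3, 3, 1, 32)), b = numeric(32))
  expect_identical(countTrainableParameters(single), 320L)
  expect_identical(as.integer(convParams(3, 3, 1, 32)), 320L)

  # full default model: per-level closed-form sum
  cfg <- networkConfig()
  cs <- c(32, 64, 128, 256, 256)
  enc <- encBlockParamCount(1, cs[1]) +
    sum(vapply(2:5, function(l) encBlockParamCount(cs[l - 1], cs[l]),
               numeric(1)))
  mlp <- sum(vapply(1:4, function(l) {
    wide <- cs[l] + 4
    4 * (cs[l] + 1) + 3 * convParams(3, 3, wide, wide) +
      convParams(3, 3, wide, cs[l])
  }, numeric(1)))
  dec <- sum(vapply(1:4, function(l) {
    convParams(3, 3, cs[l + 1] / 4, cs[l]) + encBlockParamCount(2 * cs[l], cs[l])
  }, numeric(1)))
  head <- convParams(1, 1, cs[1], 1)
  expect_identical(countTrainableParameters(buildMLPED(cfg, seed = 1)),
                   as.integer(enc + mlp + dec + head))
})

test_that("gradients match finite differences on a small network", {
  cfg <- tinyConfig()
  model <- buildMLPED(cfg, seed = 3)
  withr::with_seed(42, {
    x <- matrix(runif(16 * 16), 16, 16)
    gt <- matrix(runif(16 * 16), 16, 16)
  })
  st <- mlped:::trainStep(model@params, cfg, x, gt, training = FALSE)
  eps <- 1e-6
  probes <- withr::with_seed(7, {
    nms <- sample(names(model@params), 12)
    lapply(nms, function(nm) list(nm = nm,
                                  i = sample(length(model@params[[nm]]), 1)))
  })
  for (pr in probes) {
    p2 <- model@params
    p2[[pr$nm]][pr$i] <- p2[[pr$nm]][pr$i] + eps
    lp <- mlped:::trainStep(p2, cfg, x, gt, training = FALSE)$loss
    p2[[pr$nm]][pr$i] <- p2[[pr$nm]][pr$i] - 2 * eps
    lm <- mlped:::trainStep(p2, cfg, x, gt, training = FALSE)$loss
    fd <- (lp - lm) / (2 * eps)
    an <- st$grads[[pr$nm]][pr$i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("every trainable parameter receives gradient (no dead branches)", {
  cfg <- tinyConfig()
  model <- buildMLPED(cfg, seed = 5)
  withr::with_seed(9, {
    x <- matrix(runif(16 * 16), 16, 16)
    gt <- matrix(runif(16 * 16), 16, 16)
  })
  st <- mlped:::trainStep(model@params, cfg, x, gt, training = FALSE)
  for (nm in names(model@params))
    expect_gt(max(abs(st$grads[[nm]])), 0)
})

test_that("bilinear resize and its adjoint satisfy the dot-product identity", {
  set.seed(11)
  x <- array(rnorm(9 * 7 * 2), dim = c(9, 7, 2))
  g <- array(rnorm(21 * 16 * 2), dim = c(21, 16, 2))
  y <- mlped:::.resize_bilinear_fwd(x, 21L, 16L)
  xt <- mlped:::.resize_bilinear_bwd(g, 9L, 7L)
  expect_equal(sum(y * g), sum(x * xt), tolerance = 1e-10)
  # constant fields resize to the same constant
  cst <- array(3.25, dim = c(8, 8, 1))
  expect_lt(max(abs(mlped:::.resize_bilinear_fwd(cst, 13L, 5L) - 3.25)), 1e-12)
})

test_that("network configuration validity rules are enforced", {
  expect_error(networkConfig(rmpKernels = c(3L, 2L)), "increasing")
  expect_error(networkConfig(dropoutRate = 1), "dropoutRate")
  expect_error(networkConfig(firstChannels = 8, channelSchedule = c(8, 16)),
               "channelSchedule")
  cfg <- networkConfig()
  expect_identical(cfg@channelSchedule, c(32L, 64L, 128L, 256L, 256L))
  expect_identical(cfg@mlpLevels, 4L)
})
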
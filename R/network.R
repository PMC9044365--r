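## The multi-level pooling encoder-decoder architecture: a five-level
## encoder (channels doubling 32 -> 64 -> 128 -> 256, bottleneck reusing the
## level-4 width), four multi-level pooling modules (residual multi-kernel
## pooling + zoom-in/zoom-out) on the skip paths, and four pixel-shuffle
## decoder blocks, closed by a 1x1 output head.

#' Construct a network configuration
#'
#' Defaults reproduce the full-scale architecture: 32 first-level channels
#' doubling to 64, 128 and 256, a bottleneck that reuses the level-4 width
#' (the published parameter total of about 8 million pins this choice down),
#' residual multi-kernel pooling windows 2, 3, 5 and 6, and a
#' zoom-in/zoom-out factor of 2.
#'
#' @param firstChannels filters in the first encoder level.
#' @param encoderLevels number of encoder levels.
#' @param channelSchedule optional explicit per-level widths; the default
#'   doubles per level and repeats the penultimate width at the bottleneck.
#' @param zoomFactor zoom-in/zoom-out spatial factor.
#' @param rmpKernels strictly increasing pooling window sizes.
#' @param dropoutRate dropout probability in encoder-style blocks.
#' @param leakySlope LeakyReLU negative slope.
#' @param normKind normalization flavour (only `"instance"`).
#' @return a [NetworkConfig-class].
#' @export
networkConfig <- function(firstChannels = 32L, encoderLevels = 5L,
                          channelSchedule = NULL, zoomFactor = 2L,
                          rmpKernels = c(2L, 3L, 5L, 6L), dropoutRate = 0,
                          leakySlope = 0.2, normKind = "instance") {
  firstChannels <- as.integer(firstChannels)
  encoderLevels <- as.integer(encoderLevels)
  if (is.null(channelSchedule)) {
    channelSchedule <- firstChannels * 2L^(seq_len(encoderLevels) - 1L)
    channelSchedule[encoderLevels] <- channelSchedule[encoderLevels - 1L]
  }
  new("NetworkConfig", firstChannels = firstChannels,
      encoderLevels = encoderLevels, mlpLevels = encoderLevels - 1L,
      channelSchedule = as.integer(channelSchedule),
      zoomFactor = as.integer(zoomFactor),
      rmpKernels = as.integer(rmpKernels),
      dropoutRate = as.numeric(dropoutRate),
      leakySlope = as.numeric(leakySlope), normKind = normKind)
}

## --- parameter initialization ----------------------------------------------

initConv <- function(kh, kw, cin, cout, slope) {
  fan <- kh * kw * cin
  sd <- sqrt(2 / ((1 + slope^2) * fan))
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

encBlockParams <- function(cin, cout, slope) {
  c1 <- initConv(3L, 3L, cin, cout, slope)
  c2 <- initConv(3L, 3L, cout, cout, slope)
  list(c1.w = c1$w, c1.b = c1$b, n1.g = rep(1, cout), n1.b = numeric(cout),
       c2.w = c2$w, c2.b = c2$b, n2.g = rep(1, cout), n2.b = numeric(cout))
}

rmpParams <- function(cin, kernels, slope) {
  out <- list()
  for (j in seq_along(kernels)) {
    cv <- initConv(1L, 1L, cin, 1L, slope)
    out[[paste0("p", j, ".w")]] <- cv$w
    out[[paste0("p", j, ".b")]] <- cv$b
  }
  out
}

zoomParams <- function(ch, slope) {
  z1 <- initConv(3L, 3L, ch, ch, slope)
  z2 <- initConv(3L, 3L, ch, ch, slope)
  z3 <- initConv(3L, 3L, ch, ch, slope)
  list(z1.w = z1$w, z1.b = z1$b, z2.w = z2$w, z2.b = z2$b,
       z3.w = z3$w, z3.b = z3$b)
}

mlpParams <- function(ch, cfg) {
  wide <- ch + length(cfg@rmpKernels)
  proj <- initConv(3L, 3L, wide, ch, cfg@leakySlope)
  c(rmpParams(ch, cfg@rmpKernels, cfg@leakySlope),
    zoomParams(wide, cfg@leakySlope),
    list(proj.w = proj$w, proj.b = proj$b))
}

decBlockParams <- function(cBelow, cLevel, cfg) {
  adj <- initConv(3L, 3L, cBelow %/% 4L, cLevel, cfg@leakySlope)
  c(list(adj.w = adj$w, adj.b = adj$b),
    encBlockParams(2L * cLevel, cLevel, cfg@leakySlope))
}

prefixNames <- function(p, prefix) {
  names(p) <- paste0(prefix, ".", names(p))
  p
}

mlpedParams <- function(cfg, seed = 1L) {
  withr::with_seed(seed, {
    cs <- cfg@channelSchedule
    L <- cfg@encoderLevels
    p <- prefixNames(encBlockParams(1L, cs[1], cfg@leakySlope), "enc1")
    for (l in 2:L)
      p <- c(p, prefixNames(encBlockParams(cs[l - 1L], cs[l], cfg@leakySlope),
                            paste0("enc", l)))
    for (l in seq_len(cfg@mlpLevels))
      p <- c(p, prefixNames(mlpParams(cs[l], cfg), paste0("mlp", l)))
    for (l in rev(seq_len(cfg@mlpLevels)))
      p <- c(p, prefixNames(decBlockParams(cs[l + 1L], cs[l], cfg),
                            paste0("dec", l)))
    head <- initConv(1L, 1L, cs[1], 1L, cfg@leakySlope)
    c(p, list(head.w = head$w, head.b = head$b))
  })
}

## --- forward graph ---------------------------------------------------------

agConvNamed <- function(tape, P, prefix, x, stride = 1L, pad = 1L) {
  # standalone blocks use unprefixed parameter names
  wn <- sub("^\\.", "", paste0(prefix, ".w"))
  bn <- sub("^\\.", "", paste0(prefix, ".b"))
  agConv2d(tape, x, P[[wn]], P[[bn]], stride = stride, pad = pad)
}

encBlockForward <- function(tape, P, prefix, x, cfg, training) {
  h <- agConvNamed(tape, P, paste0(prefix, ".c1"), x)
  h <- agInstanceNorm(tape, h, P[[paste0(prefix, ".n1.g")]],
                      P[[paste0(prefix, ".n1.b")]])
  h <- agLeakyRelu(tape, h, cfg@leakySlope)
  h <- agDropout(tape, h, cfg@dropoutRate, training)
  h <- agConvNamed(tape, P, paste0(prefix, ".c2"), h)
  h <- agInstanceNorm(tape, h, P[[paste0(prefix, ".n2.g")]],
                      P[[paste0(prefix, ".n2.b")]])
  h <- agLeakyRelu(tape, h, cfg@leakySlope)
  agDropout(tape, h, cfg@dropoutRate, training)
}

rmpForward <- function(tape, P, prefix, x, kernels) {
  d <- dim(x$value)
  if (d[1] < max(kernels) || d[2] < max(kernels))
    stop("feature map (", d[1], "x", d[2], ") smaller than the largest ",
         "pooling kernel (", max(kernels), ")", call. = FALSE)
  out <- x
  for (j in seq_along(kernels)) {
    h <- agMaxPool(tape, x, kernels[j])
    h <- agConvNamed(tape, P, paste0(prefix, ".p", j), h, pad = 0L)
    h <- agResize(tape, h, d[1], d[2])
    out <- agConcat(tape, out, h)
  }
  out
}

zoomForward <- function(tape, P, prefix, x, zoom, slope) {
  d <- dim(x$value)
  if (d[1] %% zoom != 0L || d[2] %% zoom != 0L)
    stop("spatial dims (", d[1], "x", d[2], ") not divisible by the zoom ",
         "factor ", zoom, call. = FALSE)
  h <- agConvNamed(tape, P, paste0(prefix, ".z1"), x)
  h <- agLeakyRelu(tape, h, slope)
  h <- agConvNamed(tape, P, paste0(prefix, ".z2"), h, stride = zoom)
  h <- agLeakyRelu(tape, h, slope)
  h <- agResize(tape, h, d[1], d[2])
  agConvNamed(tape, P, paste0(prefix, ".z3"), h)
}

mlpForward <- function(tape, P, prefix, x, cfg) {
  h <- rmpForward(tape, P, prefix, x, cfg@rmpKernels)
  h <- zoomForward(tape, P, prefix, h, cfg@zoomFactor, cfg@leakySlope)
  h <- agConvNamed(tape, P, paste0(prefix, ".proj"), h)
  agAdd(tape, h, x)
}

decBlockForward <- function(tape, P, prefix, below, skip, cfg, training) {
  h <- agPixelShuffle(tape, below, 2L)
  h <- agConvNamed(tape, P, paste0(prefix, ".adj"), h)
  h <- agConcat(tape, h, skip)
  encBlockForward(tape, P, prefix, h, cfg, training)
}

mlpedForwardNodes <- function(tape, P, x, cfg, training) {
  L <- cfg@encoderLevels
  enc <- vector("list", L)
  enc[[1]] <- encBlockForward(tape, P, "enc1", x, cfg, training)
  for (l in 2:L) {
    down <- agAvgPool2(tape, enc[[l - 1L]])
    enc[[l]] <- encBlockForward(tape, P, paste0("enc", l), down, cfg, training)
  }
  sel <- vector("list", cfg@mlpLevels)
  for (l in seq_len(cfg@mlpLevels))
    sel[[l]] <- mlpForward(tape, P, paste0("mlp", l), enc[[l]], cfg)
  h <- enc[[L]]
  for (l in rev(seq_len(cfg@mlpLevels)))
    h <- decBlockForward(tape, P, paste0("dec", l), h, sel[[l]], cfg, training)
  agConvNamed(tape, P, "head", h, pad = 0L)
}

checkInputSize <- function(d, cfg) {
  div <- 2L^(cfg@encoderLevels - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input size ", d[1], "x", d[2], " must be divisible by ", div,
         " (one halving per encoder level)", call. = FALSE)
}

## --- exported surface ------------------------------------------------------

#' Build the full network
#'
#' Initializes all trainable parameters (He-style normal initialization
#' scaled for the LeakyReLU slope) from the given seed and returns the
#' model. The model maps a 1-channel image whose sides are divisible by
#' `2^(encoderLevels - 1)` to a 1-channel image of the same size.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer initialization seed.
#' @return an [MLPEDModel-class] in `"train"` mode.
#' @examples
#' cfg <- networkConfig(firstChannels = 8)
#' model <- buildMLPED(cfg, seed = 1)
#' countTrainableParameters(model)
#' @export
buildMLPED <- function(config = networkConfig(), seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  new("MLPEDModel", config = config, params = mlpedParams(config, seed),
      mode = "train")
}

#' Switch a model between train and eval mode
#'
#' @param model an [MLPEDModel-class].
#' @param mode `"train"` (dropout active) or `"eval"` (deterministic).
#' @return the model with the mode set.
#' @export
setMode <- function(model, mode = c("eval", "train")) {
  model@mode <- match.arg(mode)
  model
}

#' Run the network on one image
#'
#' @param model an [MLPEDModel-class].
#' @param image numeric matrix; sides divisible by
#'   `2^(encoderLevels - 1)`.
#' @param standardize standardize the input to zero mean / unit variance and
#'   undo the affine on the output (the convention used in training).
#' @return numeric matrix of the same shape.
#' @export
mlpedForward <- function(model, image, standardize = TRUE) {
  stopifnot(is(model, "MLPEDModel"), is.matrix(image))
  cfg <- model@config
  d <- dim(image)
  checkInputSize(d, cfg)
  mu <- 0; sdv <- 1
  if (standardize) {
    mu <- mean(image)
    sdv <- stats::sd(image)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
  }
  tape <- agTape()
  P <- lapply(model@params, agLeaf, tape = tape)
  x <- agLeaf(tape, array((image - mu) / sdv, dim = c(d, 1L)))
  y <- mlpedForwardNodes(tape, P, x, cfg, training = model@mode == "train")
  matrix(sdv * y$value + mu, d[1], d[2])
}

#' Count independently trainable scalars
#'
#' @param model an [MLPEDModel-class], a block built by
#'   [buildEncoderBlock()]/[buildDecoderBlock()], or a plain named list of
#'   parameter arrays.
#' @return integer parameter count.
#' @examples
#' countTrainableParameters(list())  # 0
#' @export
countTrainableParameters <- function(model) {
  p <- if (is(model, "MLPEDModel")) model@params
       else if (is.list(model) && !is.null(model$params)) model$params
       else model
  sum(vapply(p, length, integer(1)))
}

#' Build a standalone encoder block
#'
#' The elementary unit of both the encoder and decoder paths: two 3x3
#' convolutions, each followed by instance normalization, LeakyReLU and
#' dropout; spatial shape is preserved.
#'
#' @param inChannels,outChannels channel widths.
#' @param config a [NetworkConfig-class] supplying slope/dropout settings.
#' @param seed initialization seed.
#' @return a list with elements `params` and `forward(x, training = FALSE)`
#'   where `x` is an `(H, W, inChannels)` array.
#' @export
buildEncoderBlock <- function(inChannels, outChannels,
                              config = networkConfig(), seed = 1L) {
  params <- withr::with_seed(seed,
    prefixNames(encBlockParams(as.integer(inChannels),
                               as.integer(outChannels), config@leakySlope),
                "blk"))
  structure(list(
    params = params,
    forward = function(x, training = FALSE) {
      tape <- agTape()
      P <- lapply(params, agLeaf, tape = tape)
      encBlockForward(tape, P, "blk", agLeaf(tape, x), config, training)$value
    }), class = "mlpedBlock")
}

#' Build a standalone decoder block
#'
#' Pixel-shuffles the lower-level features (r = 2), adjusts channels with a
#' 3x3 convolution, concatenates the same-level selected features, and
#' applies an encoder-structure block. Spatial size doubles relative to the
#' lower level.
#'
#' @param belowChannels channel count of the lower-level features (must be
#'   divisible by 4).
#' @param levelChannels channel count at this level (of the skip features
#'   and the output).
#' @param config a [NetworkConfig-class].
#' @param seed initialization seed.
#' @return a list with elements `params` and
#'   `forward(below, skip, training = FALSE)`.
#' @export
buildDecoderBlock <- function(belowChannels, levelChannels,
                              config = networkConfig(), seed = 1L) {
  belowChannels <- as.integer(belowChannels)
  if (belowChannels %% 4L != 0L)
    stop("belowChannels must be divisible by 4 (pixel shuffle with r = 2)",
         call. = FALSE)
  params <- withr::with_seed(seed,
    prefixNames(decBlockParams(belowChannels, as.integer(levelChannels),
                               config), "blk"))
  structure(list(
    params = params,
    forward = function(below, skip, training = FALSE) {
      tape <- agTape()
      P <- lapply(params, agLeaf, tape = tape)
      decBlockForward(tape, P, "blk", agLeaf(tape, below),
                      agLeaf(tape, skip), config, training)$value
    }), class = "mlpedBlock")
}

#' Residual multi-kernel pooling
#'
#' Max-pools the input at several window sizes (stride = window), reduces
#' each pooled map to a single channel with a 1x1 convolution, upsamples it
#' bilinearly back to the input size, and concatenates all branches behind
#' the untouched input: output channels = input channels + number of
#' kernels.
#'
#' @param features `(H, W, C)` numeric array.
#' @param kernels strictly increasing pooling windows.
#' @param params optional named list of 1x1 convolution weights
#'   (`p<j>.w` of dim `c(1, 1, C, 1)` and `p<j>.b`); seeded random when
#'   omitted.
#' @param seed initialization seed used when `params` is omitted.
#' @return `(H, W, C + length(kernels))` array.
#' @export
rmp <- function(features, kernels = c(2L, 3L, 5L, 6L), params = NULL,
                seed = 1L) {
  kernels <- as.integer(kernels)
  d <- dim(features)
  if (is.null(params))
    params <- withr::with_seed(seed, rmpParams(d[3], kernels, 0.2))
  tape <- agTape()
  P <- lapply(params, agLeaf, tape = tape)
  rmpForward(tape, P, "", agLeaf(tape, features), kernels)$value
}

#' Zoom-in/zoom-out unit
#'
#' Three 3x3 convolutions: one at full resolution, one that shrinks the
#' spatial size by `zoomFactor` (strided), and one applied after bilinear
#' upsampling back to the input size. Channel count and spatial shape are
#' preserved; the unit gives a level a preview of the scale below it.
#'
#' @param features `(H, W, C)` array with spatial dims divisible by
#'   `zoomFactor`.
#' @param zoomFactor integer shrink factor.
#' @param params optional named list (`z1.w`, `z1.b`, `z2.w`, `z2.b`,
#'   `z3.w`, `z3.b`); seeded random when omitted.
#' @param seed initialization seed.
#' @param leakySlope LeakyReLU slope between the convolutions.
#' @return array of the same shape as `features`.
#' @export
zoomInOut <- function(features, zoomFactor = 2L, params = NULL, seed = 1L,
                      leakySlope = 0.2) {
  zoomFactor <- as.integer(zoomFactor)
  d <- dim(features)
  if (is.null(params))
    params <- withr::with_seed(seed, zoomParams(d[3], leakySlope))
  tape <- agTape()
  P <- lapply(params, agLeaf, tape = tape)
  zoomForward(tape, P, "", agLeaf(tape, features), zoomFactor,
              leakySlope)$value
}

#' Multi-level pooling module
#'
#' The per-level feature selector placed on the encoder-to-decoder skip
#' path: residual multi-kernel pooling, then a zoom-in/zoom-out unit, then a
#' 3x3 projection back to the level's channel count, added residually to the
#' module input. Shape-preserving.
#'
#' @param features `(H, W, C)` array.
#' @param config a [NetworkConfig-class].
#' @param params optional named parameter list (as produced internally);
#'   seeded random when omitted.
#' @param seed initialization seed.
#' @return array of the same shape as `features`.
#' @export
mlpModule <- function(features, config = networkConfig(), params = NULL,
                      seed = 1L) {
  d <- dim(features)
  if (is.null(params))
    params <- withr::with_seed(seed, mlpParams(d[3], config))
  tape <- agTape()
  P <- lapply(params, agLeaf, tape = tape)
  mlpForward(tape, P, "", agLeaf(tape, features), config)$value
}

#' Sub-pixel (pixel shuffle) upsampling
#'
#' Bijectively rearranges an `(H, W, C * r^2)` array into `(H * r, W * r,
#' C)`: output pixel `(h*r + dy, w*r + dx)` of channel `c` takes input
#' channel `c*r^2 + dy*r + dx` at `(h, w)` (0-based). Value-preserving; no
#' parameters.
#'
#' @param features `(H, W, C * r^2)` array.
#' @param r integer upsampling factor.
#' @return `(H * r, W * r, C)` array.
#' @export
pixelShuffle <- function(features, r) pixelShuffleArray(features, as.integer(r))
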
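## L1/RMSProp training loop and the NMSE/PSNR/SSIM evaluation surface.

#' Construct training settings
#'
#' The full-scale recipe is 100 epochs of RMSProp at learning rate 0.001;
#' desk-scale experiments use far fewer epochs on small phantoms.
#'
#' @param epochs passes over the training set.
#' @param learningRate RMSProp step size.
#' @param batchSize gradient-accumulation batch size.
#' @param seed integer seed (epoch shuffling, dropout).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 100L, learningRate = 0.001, batchSize = 1L,
                        seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate), optimizer = "rmsprop",
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Mean absolute error (L1 loss)
#'
#' The training objective: the mean absolute per-pixel difference between a
#' reconstruction and its ground truth (mean rather than sum, so the
#' learning rate transfers across image sizes).
#'
#' @param recon,gt numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @export
l1Loss <- function(recon, gt) {
  if (!identical(dim(recon), dim(gt)))
    stop("recon and gt must have identical shapes", call. = FALSE)
  mean(abs(recon - gt))
}

#' Normalized mean squared error
#'
#' Squared Euclidean error divided by the squared Euclidean norm of the
#' ground truth: `sum((gt - pred)^2) / sum(gt^2)`.
#'
#' @param gt ground-truth matrix (not all zero).
#' @param pred reconstruction of identical shape.
#' @return nonnegative scalar; 0 iff `pred == gt`, 1 for `pred == 0`.
#' @export
nmse <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("gt and pred must have identical shapes", call. = FALSE)
  den <- sum(gt^2)
  if (den == 0) stop("ground truth is identically zero", call. = FALSE)
  sum((gt - pred)^2) / den
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(dataRange^2 / MSE)` in decibels; `Inf` when the images are
#' identical.
#'
#' @param gt,pred numeric matrices of identical shape.
#' @param dataRange positive dynamic range; defaults to `max(gt)`.
#' @return scalar in dB (`Inf` for a perfect reconstruction).
#' @export
psnr <- function(gt, pred, dataRange = max(gt)) {
  if (!identical(dim(gt), dim(pred)))
    stop("gt and pred must have identical shapes", call. = FALSE)
  if (dataRange <= 0) stop("dataRange must be positive", call. = FALSE)
  mse <- mean((gt - pred)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

## Sums over all complete w x w windows (valid convolution with a box
## kernel) via an integral image.
winSum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  ho <- nr - w + 1L; wo <- nc - w + 1L
  I[w + seq_len(ho), w + seq_len(wo)] - I[seq_len(ho), w + seq_len(wo)] -
    I[w + seq_len(ho), seq_len(wo)] + I[seq_len(ho), seq_len(wo)]
}

#' Structural similarity index
#'
#' Mean local SSIM with a uniform `win x win` window, stabilizers
#' `C1 = (K1 * dataRange)^2`, `C2 = (K2 * dataRange)^2` and unbiased sample
#' (co)variances, evaluated over all complete windows — the convention of
#' the standard reference implementations that filter and then crop the
#' filter-radius border.
#'
#' @param gt,pred numeric matrices of identical shape, at least `win` pixels
#'   per side.
#' @param dataRange positive dynamic range; defaults to `max(gt)`.
#' @param win odd window size (default 7).
#' @param K1,K2 stabilizer constants.
#' @return scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(gt, pred, dataRange = max(gt), win = 7L, K1 = 0.01,
                 K2 = 0.03) {
  if (!identical(dim(gt), dim(pred)))
    stop("gt and pred must have identical shapes", call. = FALSE)
  if (dataRange <= 0) stop("dataRange must be positive", call. = FALSE)
  if (any(dim(gt) < win))
    stop("images (", paste(dim(gt), collapse = "x"),
         ") smaller than the SSIM window (", win, ")", call. = FALSE)
  np <- win * win
  covNorm <- np / (np - 1)
  ux <- winSum(gt, win) / np
  uy <- winSum(pred, win) / np
  uxx <- winSum(gt^2, win) / np
  uyy <- winSum(pred^2, win) / np
  uxy <- winSum(gt * pred, win) / np
  vx <- covNorm * (uxx - ux^2)
  vy <- covNorm * (uyy - uy^2)
  vxy <- covNorm * (uxy - ux * uy)
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  mean(((2 * ux * uy + C1) * (2 * vxy + C2)) /
         ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
}

#' Metrics for one reconstruction
#'
#' @param gt ground-truth matrix.
#' @param pred reconstruction.
#' @param dataRange dynamic range for PSNR/SSIM; defaults to `max(gt)`.
#' @return one-row `data.frame` with columns `nmse`, `psnr`, `ssim`.
#' @export
metricReport <- function(gt, pred, dataRange = max(gt)) {
  data.frame(nmse = nmse(gt, pred), psnr = psnr(gt, pred, dataRange),
             ssim = ssim(gt, pred, dataRange))
}

## Forward + L1 on one standardized input; returns loss node and leaf map.
trainStep <- function(params, cfg, x, gt, training) {
  mu <- mean(x)
  sdv <- stats::sd(x)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  tape <- agTape()
  P <- lapply(params, agLeaf, tape = tape)
  xin <- agLeaf(tape, array((x - mu) / sdv, dim = c(dim(x), 1L)))
  y <- mlpedForwardNodes(tape, P, xin, cfg, training)
  y <- agAffine(tape, y, sdv, mu)
  loss <- agL1(tape, y, array(gt, dim = dim(y$value)))
  agBackward(tape, loss)
  grads <- lapply(P, function(nd)
    if (is.null(nd$grad)) array(0, dim = dim(nd$value)) else nd$grad)
  list(loss = loss$value, grads = grads)
}

#' Train the network with RMSProp on an L1 objective
#'
#' Each training example is the aliased zero-filled reconstruction of its
#' masked multi-coil k-space; the target is the ground-truth magnitude
#' image. Inputs are standardized per image (zero mean, unit variance) and
#' the inverse affine is applied to the network output before the loss.
#' RMSProp uses squared-gradient averaging constant 0.99 and epsilon 1e-8
#' (the common framework defaults). Fully reproducible from `config@seed`.
#'
#' @param model an [MLPEDModel-class].
#' @param data list of [SyntheticSample-class] objects.
#' @param config a [TrainConfig-class].
#' @param verbose print the mean loss per epoch.
#' @return list with elements `model` (updated weights, `"eval"` mode) and
#'   `history` (mean L1 loss per epoch).
#' @export
trainMLPED <- function(model, data, config = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "MLPEDModel"), is(config, "TrainConfig"))
  if (length(data) == 0) stop("training data is empty", call. = FALSE)
  cfg <- model@config
  inputs <- lapply(data, function(s)
    zeroFilledRecon(s@kspace, s@mask, target = dim(s@groundTruth)))
  targets <- lapply(data, groundTruth)
  params <- model@params
  v <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  alpha <- 0.99; eps <- 1e-8
  lr <- config@learningRate
  history <- numeric(config@epochs)
  withr::with_seed(config@seed, {
    for (ep in seq_len(config@epochs)) {
      ord <- sample(length(data))
      losses <- numeric(0)
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      for (bt in batches) {
        acc <- NULL
        for (i in bt) {
          st <- trainStep(params, cfg, inputs[[i]], targets[[i]],
                          training = TRUE)
          losses <- c(losses, st$loss)
          acc <- if (is.null(acc)) st$grads
                 else mapply(`+`, acc, st$grads, SIMPLIFY = FALSE)
        }
        if (lr > 0) {
          nb <- length(bt)
          for (nm in names(params)) {
            g <- acc[[nm]] / nb
            v[[nm]] <- alpha * v[[nm]] + (1 - alpha) * g^2
            params[[nm]] <- params[[nm]] - lr * g / (sqrt(v[[nm]]) + eps)
          }
        }
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d: mean L1 loss %.6f", ep, config@epochs,
                        history[ep]))
    }
  })
  model@params <- params
  model@mode <- "eval"
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate reconstructions on a synthetic dataset
#'
#' Runs the model (in deterministic eval mode) on the zero-filled input of
#' each sample and scores it against the ground truth; `reconstruction =
#' "zero_filled"` scores the aliased input itself, the classical baseline.
#' Metrics are computed per slice; with `grouping = "per_volume"` they are
#' averaged within each volume first (the synthetic samples are single-slice
#' volumes, so the two groupings coincide there). The PSNR/SSIM dynamic
#' range is the maximum of each volume's ground truth.
#'
#' @param model an [MLPEDModel-class].
#' @param data list of [SyntheticSample-class] objects.
#' @param grouping `"per_volume"` or `"per_slice"`.
#' @param reconstruction `"network"` or `"zero_filled"`.
#' @return `data.frame` with columns `volume`, `nmse`, `psnr`, `ssim`.
#' @export
evaluateModel <- function(model, data,
                          grouping = c("per_volume", "per_slice"),
                          reconstruction = c("network", "zero_filled")) {
  grouping <- match.arg(grouping)
  reconstruction <- match.arg(reconstruction)
  if (length(data) == 0) stop("no data to evaluate", call. = FALSE)
  model <- setMode(model, "eval")
  rows <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    gt <- s@groundTruth
    x <- zeroFilledRecon(s@kspace, s@mask, target = dim(gt))
    pred <- if (reconstruction == "network") mlpedForward(model, x) else x
    cbind(volume = i, metricReport(gt, pred, dataRange = max(gt)))
  })
  out <- do.call(rbind, rows)
  if (grouping == "per_volume")
    out <- stats::aggregate(out[c("nmse", "psnr", "ssim")],
                            by = out["volume"], FUN = mean)
  out
}

#' Write a metrics table as TSV
#'
#' @param report `data.frame` from [evaluateModel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetricsTable <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
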
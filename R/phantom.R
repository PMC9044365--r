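## Synthetic multi-coil data generator.  Ellipse-sum phantoms stand in for
## anatomy; smooth ring-of-coils sensitivity profiles reproduce the
## inhomogeneous coil brightness of a 15-channel knee array; the two
## contrast styles mimic clean proton-density and speckled fat-suppressed
## acquisitions.

#' Construct phantom generation settings
#'
#' @param size integer `(rows, columns)`; default `c(64, 64)` (desk-scale;
#'   `c(320, 320)` matches the crop size used with real scans).
#' @param nEllipses number of ellipses; the first is always a large centered
#'   axis-aligned ellipse (the "anatomy outline"), the rest are random.
#' @param contrast `"pd_like"` (clean) or `"pdfs_like"` (speckled).
#' @param speckleSd log-normal speckle standard deviation for
#'   `"pdfs_like"`; ignored otherwise.
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(size = c(64L, 64L), nEllipses = 6L,
                        contrast = c("pd_like", "pdfs_like"),
                        speckleSd = 0.2, seed = 1L) {
  new("PhantomSpec", size = as.integer(size),
      nEllipses = as.integer(nEllipses), contrast = match.arg(contrast),
      speckleSd = as.numeric(speckleSd), seed = as.integer(seed))
}

#' Generate an ellipse-sum phantom image
#'
#' Sums `nEllipses` positive-intensity ellipses on a zero background over the
#' normalized square `[-1, 1]^2` and clips to `[0, 1]`. The first ellipse is
#' a fixed large centered axis-aligned one so every phantom has a compact
#' support away from the borders; the remaining ellipses are randomly placed,
#' sized and rotated inside it. The `"pdfs_like"` contrast multiplies the
#' result by seeded log-normal speckle and adds a small half-normal
#' background texture, mimicking fat-suppression noise in foreground and
#' background.
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric matrix in `[0, 1]` of shape `spec@size`.
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nr <- spec@size[1]; nc <- spec@size[2]
  y <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  x <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  withr::with_seed(spec@seed, {
    img <- matrix(0, nr, nc)
    for (e in seq_len(spec@nEllipses)) {
      if (e == 1L) {
        cx <- 0; cy <- 0; a <- 0.7; b <- 0.6; th <- 0; amp <- 0.45
      } else {
        cx <- stats::runif(1, -0.45, 0.45)
        cy <- stats::runif(1, -0.45, 0.45)
        a <- stats::runif(1, 0.08, 0.35)
        b <- stats::runif(1, 0.08, 0.35)
        th <- stats::runif(1, 0, pi)
        amp <- stats::runif(1, -0.3, 0.5)
      }
      xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
      yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
      img <- img + amp * ((xr / a)^2 + (yr / b)^2 <= 1)
    }
    img <- pmin(pmax(img, 0), 1)
    if (spec@contrast == "pdfs_like" && spec@speckleSd > 0) {
      speckle <- exp(matrix(stats::rnorm(nr * nc, sd = spec@speckleSd), nr, nc))
      floor_tex <- abs(matrix(stats::rnorm(nr * nc, sd = 0.05 * spec@speckleSd),
                              nr, nc))
      img <- pmin(pmax(img * speckle + floor_tex, 0), 1)
    }
    img
  })
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Places `nCoils` virtual receiver coils on a ring just outside the image
#' and gives each a Gaussian magnitude profile peaked towards its coil (the
#' closer the tissue, the stronger the signal) plus a smooth random linear
#' phase ramp. The set is jointly normalized so the per-pixel sum of squared
#' magnitudes equals 1, making root-sum-of-squares combination exact on
#' noiseless data.
#'
#' @param nCoils number of coils (>= 1); 15 matches a typical knee array.
#' @param size integer `(rows, columns)`.
#' @param seed integer seed (ring jitter and phase ramps).
#' @return a normalized [CoilSensitivitySet-class].
#' @export
makeCoilSensitivities <- function(nCoils, size, seed = 1L) {
  nCoils <- as.integer(nCoils)
  if (nCoils < 1L) stop("nCoils must be >= 1", call. = FALSE)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  y <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  x <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  maps <- array(0i, dim = c(nr, nc, nCoils))
  withr::with_seed(seed, {
    angles <- 2 * pi * (seq_len(nCoils) - 1) / nCoils +
      stats::runif(nCoils, -0.1, 0.1)
    for (i in seq_len(nCoils)) {
      cx <- 1.3 * cos(angles[i]); cy <- 1.3 * sin(angles[i])
      g <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * 0.9^2))
      ramp <- stats::runif(2, -1, 1)
      phase <- ramp[1] * x + ramp[2] * y + stats::runif(1, 0, 2 * pi)
      maps[, , i] <- g * exp(1i * phase)
    }
  })
  norm <- sqrt(rowSums(matrix(Mod(maps)^2, nrow = nr * nc)))
  maps <- maps / array(norm, dim = dim(maps))
  new("CoilSensitivitySet", maps = maps, normalized = TRUE)
}

#' Simulate a collection of accelerated multi-coil acquisitions
#'
#' For each sample: generate a phantom, acquire it through seeded coil
#' sensitivities with complex Gaussian k-space noise, draw a fresh random
#' column mask at the requested acceleration, and store the masked k-space
#' together with the ground truth. Per-sample seeds are derived
#' deterministically from the master seed, so the whole collection is
#' bit-reproducible.
#'
#' @param nSamples number of samples (>= 1).
#' @param spec a [PhantomSpec-class]; its `seed` slot is overridden per
#'   sample.
#' @param nCoils number of receiver coils.
#' @param accel integer acceleration factor.
#' @param noiseSd k-space noise standard deviation per component.
#' @param seed master seed.
#' @param maskKind `"random"` (default) or `"equispaced"`.
#' @return list of [SyntheticSample-class] objects.
#' @export
simulateDataset <- function(nSamples, spec = phantomSpec(), nCoils = 15L,
                            accel = 4L, noiseSd = 0, seed = 1L,
                            maskKind = "random") {
  nSamples <- as.integer(nSamples)
  stopifnot(nSamples >= 1L, is(spec, "PhantomSpec"))
  accel <- as.integer(accel)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(2147483582L, nSamples * 4L), nrow = 4L))
  lapply(seq_len(nSamples), function(k) {
    sspec <- spec
    sspec@seed <- seeds[1L, k]
    gt <- makePhantom(sspec)
    sens <- makeCoilSensitivities(nCoils, spec@size, seed = seeds[2L, k])
    ks <- applySensitivities(gt, sens, noiseSd = noiseSd, seed = seeds[3L, k])
    mask <- makeMask(spec@size[2], accel, kind = maskKind, seed = seeds[4L, k])
    new("SyntheticSample", groundTruth = gt, kspace = applyMask(ks, mask),
        sensitivities = sens, mask = mask, acceleration = accel)
  })
}
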
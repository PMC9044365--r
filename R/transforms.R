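## Deterministic signal-processing layer: centered orthonormal Fourier
## transforms, the coil-sensitivity acquisition model, Cartesian column
## masks, root-sum-of-squares combination, center cropping, and the
## zero-filled reconstruction that feeds the network.

circshift <- function(m, by) {
  n <- dim(m)
  i <- (seq_len(n[1]) - 1L - by[1]) %% n[1] + 1L
  j <- (seq_len(n[2]) - 1L - by[2]) %% n[2] + 1L
  m[i, j, drop = FALSE]
}

fftshift2 <- function(m) circshift(m, floor(dim(m) / 2))
ifftshift2 <- function(m) circshift(m, ceiling(dim(m) / 2))

.check2d <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop(what, " must be a 2-D array", call. = FALSE)
}

#' Centered orthonormal 2-D Fourier transform
#'
#' Forward transform from image space to k-space with the DC component at the
#' array center (`floor(n/2)` in 0-based indexing along each axis) and
#' orthonormal `1/sqrt(N)` scaling, so that [ifft2c()] is the exact inverse
#' and energy is conserved (Parseval).
#'
#' @param image numeric or complex matrix.
#' @return complex matrix of the same shape.
#' @examples
#' x <- matrix(stats::rnorm(16), 4, 4)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(image) {
  .check2d(image, "image")
  fftshift2(stats::fft(ifftshift2(image))) / sqrt(length(image))
}

#' Centered orthonormal 2-D inverse Fourier transform
#'
#' @param kspace complex matrix with the DC component at the array center.
#' @return complex matrix of the same shape.
#' @export
ifft2c <- function(kspace) {
  .check2d(kspace, "kspace")
  fftshift2(stats::fft(ifftshift2(kspace), inverse = TRUE)) /
    sqrt(length(kspace))
}

#' Simulate a multi-coil acquisition of one image
#'
#' Implements the parallel-imaging forward model: coil i records
#' `F(S_i * x) + noise_i`, where `F` is the centered orthonormal Fourier
#' transform, `S_i` the complex coil sensitivity, and the measurement noise
#' has independent zero-mean Gaussian real and imaginary parts of standard
#' deviation `noiseSd` at every k-space sample.
#'
#' @param image numeric (magnitude) or complex matrix.
#' @param sens a [CoilSensitivitySet-class] with the same spatial shape.
#' @param noiseSd nonnegative noise standard deviation per component.
#' @param seed integer seed making the noise reproducible.
#' @return a single-slice [KSpaceVolume-class].
#' @export
applySensitivities <- function(image, sens, noiseSd = 0, seed = 1L) {
  .check2d(image, "image")
  stopifnot(is(sens, "CoilSensitivitySet"), noiseSd >= 0)
  maps <- sensMaps(sens)
  if (!identical(dim(image), dim(maps)[1:2]))
    stop("image and sensitivity maps must share the spatial shape",
         call. = FALSE)
  nc <- dim(maps)[3]
  ks <- array(0i, dim = c(dim(image), nc, 1L))
  for (i in seq_len(nc)) ks[, , i, 1L] <- fft2c(maps[, , i] * image)
  if (noiseSd > 0) {
    noise <- withr::with_seed(seed, {
      n <- length(ks)
      complex(real = stats::rnorm(n, sd = noiseSd),
              imaginary = stats::rnorm(n, sd = noiseSd))
    })
    ks <- ks + array(noise, dim = dim(ks))
  }
  new("KSpaceVolume", data = ks)
}

#' Root-sum-of-squares coil combination
#'
#' Combines per-coil images into one magnitude image without explicit
#' sensitivity knowledge: per pixel,
#' `x_combine = sqrt(sum_i |x_i|^2)`.
#'
#' @param coilImages complex (or numeric) array `dim = c(rows, cols, coils)`.
#' @return nonnegative numeric matrix `rows x cols`.
#' @export
rssCombine <- function(coilImages) {
  d <- dim(coilImages)
  if (is.null(d) || length(d) != 3L)
    stop("coilImages must be a 3-D array (rows, columns, coils)",
         call. = FALSE)
  if (d[3] < 1L) stop("need at least one coil", call. = FALSE)
  matrix(sqrt(rowSums(matrix(Mod(coilImages)^2, nrow = d[1] * d[2]))),
         d[1], d[2])
}

#' Build a Cartesian column-sampling mask
#'
#' A central block of `round(centerFraction * columns)` consecutive columns is
#' always fully sampled (the low-frequency auto-calibration region). For
#' `kind = "random"` the total number of sampled columns is exactly
#' `round(columns / acceleration)`; the non-central ones are drawn uniformly
#' without replacement. For `kind = "equispaced"` the non-central columns are
#' taken on a stride-`acceleration` grid starting at offset
#' `seed %% acceleration`. `acceleration = 1` samples everything.
#'
#' @param columns number of k-space columns.
#' @param acceleration integer acceleration factor (>= 1).
#' @param centerFraction fraction of columns in the fully sampled center.
#'   Default `0.32 / acceleration`, i.e. 0.08 at 4-fold and 0.04 at 8-fold.
#' @param kind `"random"` or `"equispaced"`.
#' @param seed integer seed.
#' @return a [SamplingMask-class].
#' @examples
#' m <- makeMask(320, 4, kind = "random", seed = 42)
#' sum(maskVector(m))  # exactly 80
#' @export
makeMask <- function(columns, acceleration, centerFraction = NULL,
                     kind = c("random", "equispaced"), seed = 1L) {
  kind <- match.arg(kind)
  columns <- as.integer(columns)
  acceleration <- as.integer(acceleration)
  stopifnot(columns >= 1L, acceleration >= 1L)
  if (is.null(centerFraction))
    centerFraction <- if (acceleration == 1L) 0 else 0.32 / acceleration
  stopifnot(centerFraction >= 0, centerFraction <= 1)

  cols <- integer(columns)
  if (acceleration == 1L) {
    cols[] <- 1L
  } else {
    nCenter <- round(centerFraction * columns)
    budget <- round(columns / acceleration)
    if (nCenter > budget)
      stop("center block (", nCenter, " columns) exceeds the sampling ",
           "budget (", budget, " columns)", call. = FALSE)
    center <- integer(0)
    if (nCenter > 0) {
      start <- floor((columns - nCenter) / 2) + 1L
      center <- seq.int(start, length.out = nCenter)
      cols[center] <- 1L
    }
    if (kind == "random") {
      pool <- setdiff(seq_len(columns), center)
      extra <- budget - nCenter
      if (extra > 0)
        cols[withr::with_seed(seed, sample(pool, extra))] <- 1L
    } else {
      offset <- seed %% acceleration
      cols[seq.int(offset + 1L, columns, by = acceleration)] <- 1L
    }
  }
  new("SamplingMask", columns = cols, acceleration = acceleration,
      centerFraction = as.numeric(centerFraction), kind = kind)
}

#' Zero out unsampled k-space columns
#'
#' Emulates accelerated acquisition by dropping the phase-encoding columns
#' the mask does not select, in every slice and coil. Idempotent.
#'
#' @param kspace a [KSpaceVolume-class].
#' @param mask a [SamplingMask-class] whose length matches the column count.
#' @return a [KSpaceVolume-class] with unsampled columns set to zero.
#' @export
applyMask <- function(kspace, mask) {
  stopifnot(is(kspace, "KSpaceVolume"), is(mask, "SamplingMask"))
  d <- dim(kspace@data)
  m <- maskVector(mask)
  if (length(m) != d[2])
    stop("mask length (", length(m), ") does not match the k-space column ",
         "count (", d[2], ")", call. = FALSE)
  keep <- array(rep(rep(m, each = d[1]), d[3] * d[4]), dim = d)
  new("KSpaceVolume", data = kspace@data * keep)
}

#' Center crop
#'
#' Returns the centrally aligned `target`-shaped window. For odd margins the
#' leading margin is `floor((in - out) / 2)`, i.e. the extra row/column is
#' dropped from the trailing side.
#'
#' @param image matrix (numeric or complex).
#' @param target integer `(rows, columns)` of the output.
#' @return matrix of shape `target`.
#' @export
centerCrop <- function(image, target) {
  .check2d(image, "image")
  target <- as.integer(target)
  d <- dim(image)
  if (any(target > d))
    stop("crop target (", paste(target, collapse = "x"),
         ") exceeds the input shape (", paste(d, collapse = "x"), ")",
         call. = FALSE)
  r0 <- floor((d[1] - target[1]) / 2)
  c0 <- floor((d[2] - target[2]) / 2)
  image[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
}

#' Zero-filled reconstruction
#'
#' The classical aliased reconstruction that forms the network input: mask
#' the k-space, inverse-transform each coil, combine with root sum of
#' squares, and center-crop. With a fully sampled mask, noiseless data and
#' normalized sensitivities this recovers the cropped ground-truth magnitude.
#'
#' @param kspace a [KSpaceVolume-class].
#' @param mask a [SamplingMask-class].
#' @param target integer `(rows, columns)` crop size; default = full size.
#' @param drop drop the slice dimension when there is a single slice.
#' @return numeric matrix (single slice, `drop = TRUE`) or 3-D array
#'   `(rows, columns, slices)`.
#' @export
zeroFilledRecon <- function(kspace, mask, target = NULL, drop = TRUE) {
  stopifnot(is(kspace, "KSpaceVolume"))
  masked <- applyMask(kspace, mask)
  d <- dim(masked@data)
  if (is.null(target)) target <- d[1:2]
  target <- as.integer(target)
  out <- array(0, dim = c(target, d[4]))
  for (s in seq_len(d[4])) {
    imgs <- array(0i, dim = c(d[1], d[2], d[3]))
    for (i in seq_len(d[3])) imgs[, , i] <- ifft2c(masked@data[, , i, s])
    out[, , s] <- centerCrop(rssCombine(imgs), target)
  }
  if (drop && d[4] == 1L) out[, , 1L] else out
}
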
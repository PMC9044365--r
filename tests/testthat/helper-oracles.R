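# Independent brute-force oracles used to pin down the fast implementations.

# Centered orthonormal 2-D DFT by the O(N^4) double sum: DC lives at
# 0-based index floor(n/2) on each axis both in image and frequency space.
dft2cOracle <- function(x) {
  M <- nrow(x); N <- ncol(x)
  m0 <- floor(M / 2); n0 <- floor(N / 2)
  out <- matrix(0i, M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
    acc <- 0i
    for (m in 0:(M - 1)) for (n in 0:(N - 1))
      acc <- acc + x[m + 1, n + 1] *
        exp(-2i * pi * ((m - m0) * (u - m0) / M + (n - n0) * (v - n0) / N))
    out[u + 1, v + 1] <- acc
  }
  out / sqrt(M * N)
}

# Per-pixel root-sum-of-squares by explicit looping.
rssOracle <- function(coils) {
  d <- dim(coils)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- 0
    for (k in seq_len(d[3])) s <- s + Mod(coils[i, j, k])^2
    out[i, j] <- sqrt(s)
  }
  out
}

# Direct 3x3 same-padding convolution (stride 1) by explicit looping.
convOracle <- function(x, w, b) {
  d <- dim(x); kd <- dim(w)
  pad <- (kd[1] - 1) / 2
  out <- array(0, dim = c(d[1], d[2], kd[4]))
  for (co in seq_len(kd[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- b[co]
    for (ci in seq_len(d[3])) for (kr in seq_len(kd[1])) for (kc in seq_len(kd[2])) {
      ir <- i + kr - 1 - pad; ic <- j + kc - 1 - pad
      if (ir >= 1 && ir <= d[1] && ic >= 1 && ic <= d[2])
        acc <- acc + x[ir, ic, ci] * w[kr, kc, ci, co]
    }
    out[i, j, co] <- acc
  }
  out
}

# Non-overlapping k x k max pooling by explicit looping.
maxpoolOracle <- function(x, k) {
  d <- dim(x)
  ho <- d[1] %/% k; wo <- d[2] %/% k
  out <- array(0, dim = c(ho, wo, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo))
    out[i, j, c] <- max(x[(i - 1) * k + seq_len(k), (j - 1) * k + seq_len(k), c])
  out
}

# Mean local SSIM over every complete win x win window, by explicit looping
# with unbiased (co)variances.
ssimOracle <- function(gt, pred, dataRange, win = 7L, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * dataRange)^2; C2 <- (K2 * dataRange)^2
  vals <- c()
  for (i in seq_len(nrow(gt) - win + 1)) for (j in seq_len(ncol(gt) - win + 1)) {
    a <- gt[i + seq_len(win) - 1, j + seq_len(win) - 1]
    b <- pred[i + seq_len(win) - 1, j + seq_len(win) - 1]
    va <- stats::var(as.numeric(a)); vb <- stats::var(as.numeric(b))
    vab <- stats::cov(as.numeric(a), as.numeric(b))
    vals <- c(vals, ((2 * mean(a) * mean(b) + C1) * (2 * vab + C2)) /
                ((mean(a)^2 + mean(b)^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# Closed-form parameter arithmetic: conv kh x kw with bias + affine
# instance norms.
convParams <- function(kh, kw, cin, cout) kh * kw * cin * cout + cout
encBlockParamCount <- function(cin, cout)
  convParams(3, 3, cin, cout) + convParams(3, 3, cout, cout) + 2 * (2 * cout)

randomComplexMatrix <- function(n, m = n, seed = 1) {
  withr::with_seed(seed,
    matrix(complex(real = stats::rnorm(n * m),
                   imaginary = stats::rnorm(n * m)), n, m))
}

# Small network configuration for fast gradient / shape tests (inputs of
# 16 x 16 and up).
tinyConfig <- function(firstChannels = 4L)
  networkConfig(firstChannels = firstChannels, encoderLevels = 3L,
                rmpKernels = c(2L, 3L))
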
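# mlped

Accelerated MRI reconstruction with a multi-level pooling encoder-decoder
network, in R.

MR scanners acquire data in k-space (the 2-D Fourier domain) line by line;
skipping phase-encoding lines shortens the scan but the inverse transform
of the under-sampled data is corrupted by aliasing. `mlped` implements the
full study pipeline for learned de-aliasing of multi-coil Cartesian
acquisitions, for researchers who want to experiment with the method
without external data or GPUs:

* **Acquisition model** — coil `i` records `k_i = F(S_i x) + α_i` with
  smooth complex sensitivities `S_i` and complex Gaussian noise `α_i`;
  `F` is the centered orthonormal 2-D Fourier transform (`fft2c`/`ifft2c`).
  Coil images combine by root sum of squares,
  `x_combine = (Σ_n |x_n|²)^{1/2}`.
* **Under-sampling** — random or equispaced column masks at acceleration
  `R` keep exactly `round(columns / R)` columns, always including a fully
  sampled low-frequency center (fraction `0.32 / R` of columns).
* **Synthetic data** — seeded ellipse phantoms (clean "PD-like" or
  speckled "PDFS-like" contrast) acquired through 15 simulated ring coils.
* **Network** — a five-level encoder (32, 64, 128, 256, 256 channels) with
  residual multi-kernel pooling + zoom-in/zoom-out modules on the skip
  paths and pixel-shuffle decoders; 8,212,513 trainable parameters in the
  default configuration (≈ 8 M). Forward and backward passes run on
  compiled im2col/GEMM kernels under a small reverse-mode tape.
* **Training / evaluation** — L1 objective
  `M(x_recon, x_gt) = ||x_recon − x_gt||₁` minimized with RMSProp
  (lr 0.001); NMSE, PSNR and SSIM scoring; fastMRI-dialect HDF5 volume
  I/O and a command-line interface.

## Worked example

Train the reduced network on 64 × 64 phantoms at 4-fold acceleration
(200 RMSProp steps, about a minute on one CPU) and compare it with the
classical zero-filled reconstruction on held-out phantoms:

```r
library(mlped)

spec  <- phantomSpec(size = c(64L, 64L))
train <- simulateDataset(20, spec, nCoils = 15, accel = 4, seed = 101)
test  <- simulateDataset(8,  spec, nCoils = 15, accel = 4, seed = 999)

model <- buildMLPED(networkConfig(firstChannels = 8), seed = 11)
fit   <- trainMLPED(model, train, trainConfig(epochs = 10, seed = 11))
round(fit$history, 4)
#>  [1] 0.0849 0.0454 0.0415 0.0370 0.0350 0.0332 0.0316 0.0309 0.0294 0.0285

zf <- evaluateModel(fit$model, test, reconstruction = "zero_filled")
nn <- evaluateModel(fit$model, test, reconstruction = "network")
round(c(zeroFilled = mean(zf$psnr), network = mean(nn$psnr)), 2)
#> zeroFilled    network
#>      21.42      24.68
```

The epoch-mean L1 loss falls monotonically, and the network reconstruction
exceeds the aliased zero-filled baseline by about 3 dB mean PSNR on
held-out phantoms (NMSE drops from 0.067 to 0.032). `evaluateModel()`
returns one row per volume with `nmse`, `psnr` and `ssim` columns;
`writeMetricsTable()` saves it as TSV.

The same pipeline is scriptable from a shell (see `inst/exec/mlped`):

```sh
mlped simulate --n 4 --coils 15 --accel 4 --seed 7 --out data/
mlped train --config run.yaml --out model.rds
mlped evaluate --checkpoint model.rds --config run.yaml --out metrics.tsv
mlped reconstruct --input data/sample_001.h5 --accel 4 --out recon.h5
```

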
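#' @import methods
NULL

#' Multi-coil k-space volume
#'
#' Container for complex frequency-domain samples of a multi-coil Cartesian
#' acquisition. The array layout is `dim = c(rows, columns, coils, slices)`;
#' this is the spatial-frequency object the scanner measures, one 2-D k-space
#' plane per coil and slice. The on-disk fastMRI dialect orders the axes
#' (slices, coils, rows, columns); [readVolume()] / [writeVolume()] translate.
#'
#' @slot data complex 4-D array, `dim = c(rows, columns, coils, slices)`.
#' @seealso [applySensitivities()], [applyMask()], [zeroFilledRecon()]
#' @export
setClass("KSpaceVolume", representation(data = "array"))

setValidity("KSpaceVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-D array (rows, columns, coils, slices)")
  if (!is.complex(object@data)) return("data must be complex")
  if (d[3] < 1L) return("coil count must be >= 1")
  if (any(!is.finite(Re(object@data))) || any(!is.finite(Im(object@data))))
    return("k-space values must be finite")
  TRUE
})

#' Coil sensitivity map set
#'
#' Smooth complex per-coil weighting maps: coil i sees `S_i * x` where `x` is
#' the underlying image. When `normalized` is `TRUE` the per-pixel sum of
#' squared magnitudes over coils is 1, so root-sum-of-squares combination of
#' the noiseless coil images recovers `|x|` exactly.
#'
#' @slot maps complex 3-D array, `dim = c(rows, columns, coils)`.
#' @slot normalized logical flag; see Details.
#' @export
setClass("CoilSensitivitySet",
         representation(maps = "array", normalized = "logical"))

setValidity("CoilSensitivitySet", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3L)
    return("maps must be a 3-D array (rows, columns, coils)")
  if (!is.complex(object@maps)) return("maps must be complex")
  if (isTRUE(object@normalized)) {
    ssq <- rowSums(matrix(Mod(object@maps)^2, nrow = d[1] * d[2]))
    if (max(abs(ssq - 1)) > 1e-6)
      return("normalized maps must satisfy sum_i |S_i|^2 = 1 per pixel")
  }
  TRUE
})

#' Cartesian column-sampling mask
#'
#' Binary phase-encoding (column) selection pattern for accelerated
#' acquisition. A fully sampled low-frequency block of
#' `round(centerFraction * length(columns))` consecutive central columns is
#' always kept; the remainder of the sampling budget is spent randomly or on
#' an equispaced grid.
#'
#' @slot columns integer 0/1 vector, one entry per k-space column.
#' @slot acceleration integer acceleration factor (1 = fully sampled).
#' @slot centerFraction fraction of columns in the fully sampled center.
#' @slot kind `"random"` or `"equispaced"`.
#' @seealso [makeMask()], [applyMask()]
#' @export
setClass("SamplingMask",
         representation(columns = "integer", acceleration = "integer",
                        centerFraction = "numeric", kind = "character"))

setValidity("SamplingMask", function(object) {
  if (!all(object@columns %in% c(0L, 1L))) return("mask entries must be 0/1")
  if (object@acceleration < 1L) return("acceleration must be >= 1")
  if (object@centerFraction < 0 || object@centerFraction > 1)
    return("centerFraction must lie in [0, 1]")
  if (!object@kind %in% c("random", "equispaced"))
    return("kind must be 'random' or 'equispaced'")
  TRUE
})

#' Network architecture configuration
#'
#' All hyperparameters of the multi-level pooling encoder-decoder network:
#' a five-level encoder whose channel widths double per level, four
#' multi-level pooling modules (residual multi-kernel pooling followed by a
#' zoom-in/zoom-out unit), and four pixel-shuffle decoder blocks.
#'
#' @slot firstChannels filters in the first encoder level (default 32).
#' @slot encoderLevels number of encoder levels (default 5).
#' @slot mlpLevels number of multi-level pooling modules (encoderLevels - 1).
#' @slot channelSchedule integer vector of per-level widths.
#' @slot zoomFactor spatial shrink factor of the zoom-in/zoom-out unit.
#' @slot rmpKernels pooling window sizes of the residual multi-kernel pooling.
#' @slot dropoutRate dropout probability inside encoder-style blocks.
#' @slot leakySlope negative slope of the LeakyReLU activations.
#' @slot normKind normalization flavour; only `"instance"` is implemented.
#' @seealso [networkConfig()], [buildMLPED()]
#' @export
setClass("NetworkConfig",
         representation(firstChannels = "integer", encoderLevels = "integer",
                        mlpLevels = "integer", channelSchedule = "integer",
                        zoomFactor = "integer", rmpKernels = "integer",
                        dropoutRate = "numeric", leakySlope = "numeric",
                        normKind = "character"))

setValidity("NetworkConfig", function(object) {
  if (object@encoderLevels != object@mlpLevels + 1L)
    return("encoderLevels must equal mlpLevels + 1")
  if (length(object@channelSchedule) != object@encoderLevels)
    return("channelSchedule length must equal encoderLevels")
  if (object@channelSchedule[1] != object@firstChannels)
    return("channelSchedule[1] must equal firstChannels")
  if (any(diff(object@rmpKernels) <= 0))
    return("rmpKernels must be strictly increasing")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  if (object@leakySlope <= 0) return("leakySlope must be positive")
  if (!identical(object@normKind, "instance"))
    return("only instance normalization is implemented")
  if (any(object@channelSchedule[-1] %% 4L != 0L))
    return("channel widths above level 1 must be divisible by 4 (pixel shuffle)")
  if (object@zoomFactor < 1L) return("zoomFactor must be >= 1")
  TRUE
})

#' Multi-level pooling encoder-decoder model
#'
#' A constructed network: its configuration, the named list of trainable
#' parameter arrays, and the mode flag controlling dropout (`"train"`) or
#' deterministic inference (`"eval"`).
#'
#' @slot config a [NetworkConfig-class].
#' @slot params named list of numeric parameter arrays.
#' @slot mode `"train"` or `"eval"`.
#' @seealso [buildMLPED()], [mlpedForward()], [trainMLPED()]
#' @export
setClass("MLPEDModel",
         representation(config = "NetworkConfig", params = "list",
                        mode = "character"))

setValidity("MLPEDModel", function(object) {
  if (!object@mode %in% c("train", "eval"))
    return("mode must be 'train' or 'eval'")
  TRUE
})

#' Phantom generation settings
#'
#' Settings for the ellipse-sum phantom generator: image size, number of
#' ellipses, contrast style (`"pd_like"` for clean proton-density-weighted
#' images, `"pdfs_like"` for the speckled fat-suppressed style) and the
#' speckle level used by the latter.
#'
#' @slot size integer `(rows, columns)`, at least 32 x 32.
#' @slot nEllipses number of ellipses summed into the phantom.
#' @slot contrast `"pd_like"` or `"pdfs_like"`.
#' @slot speckleSd standard deviation of the log-normal speckle field.
#' @slot seed integer seed making the phantom reproducible.
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
         representation(size = "integer", nEllipses = "integer",
                        contrast = "character", speckleSd = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@size) != 2L || any(object@size < 32L))
    return("size must be (rows, columns) with both >= 32")
  if (object@nEllipses < 1L) return("nEllipses must be >= 1")
  if (!object@contrast %in% c("pd_like", "pdfs_like"))
    return("contrast must be 'pd_like' or 'pdfs_like'")
  if (object@speckleSd < 0) return("speckleSd must be >= 0")
  TRUE
})

#' One simulated multi-coil acquisition
#'
#' A ground-truth magnitude image together with the masked multi-coil
#' k-space that a simulated accelerated scan of it would record, the coil
#' sensitivities used, and the sampling mask.
#'
#' @slot groundTruth numeric matrix, the noiseless magnitude image.
#' @slot kspace a [KSpaceVolume-class] (already masked).
#' @slot sensitivities a [CoilSensitivitySet-class].
#' @slot mask a [SamplingMask-class].
#' @slot acceleration integer acceleration factor.
#' @seealso [simulateDataset()]
#' @export
setClass("SyntheticSample",
         representation(groundTruth = "matrix", kspace = "KSpaceVolume",
                        sensitivities = "CoilSensitivitySet",
                        mask = "SamplingMask", acceleration = "integer"))

setValidity("SyntheticSample", function(object) {
  if (coilCount(object@kspace) != coilCount(object@sensitivities))
    return("kspace and sensitivities disagree on the coil count")
  TRUE
})

#' Training settings
#'
#' @slot epochs number of passes over the training set.
#' @slot learningRate RMSProp step size.
#' @slot optimizer only `"rmsprop"` is implemented.
#' @slot batchSize gradient-accumulation batch size.
#' @slot seed integer seed for shuffling and dropout.
#' @seealso [trainConfig()], [trainMLPED()]
#' @export
setClass("TrainConfig",
         representation(epochs = "integer", learningRate = "numeric",
                        optimizer = "character", batchSize = "integer",
                        seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@learningRate < 0) return("learningRate must be >= 0")
  if (!identical(object@optimizer, "rmsprop"))
    return("only the rmsprop optimizer is implemented")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  TRUE
})

#' On-disk multi-coil volume record
#'
#' The in-memory form of one fastMRI-dialect HDF5 file: the k-space volume,
#' the optional root-sum-of-squares reference stack, and the string
#' attributes (e.g. the acquisition label).
#'
#' @slot kspace a [KSpaceVolume-class].
#' @slot rssReference numeric array `(rows, columns, slices)` or a 0-length
#'   array when absent.
#' @slot attributes named character vector.
#' @seealso [readVolume()], [writeVolume()]
#' @export
setClass("VolumeRecord",
         representation(kspace = "KSpaceVolume", rssReference = "array",
                        attributes = "character"))

setValidity("VolumeRecord", function(object) {
  if (length(object@rssReference) > 0) {
    d <- dim(object@rssReference)
    if (length(d) != 3L)
      return("rssReference must be (rows, columns, slices)")
    if (d[3] != sliceCount(object@kspace))
      return("rssReference slice count must match the k-space slice count")
  }
  TRUE
})
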
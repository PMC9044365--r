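#' Number of receiver coils
#'
#' @param x a [KSpaceVolume-class] or [CoilSensitivitySet-class].
#' @return integer coil count.
#' @export
setGeneric("coilCount", function(x) standardGeneric("coilCount"))

#' @rdname coilCount
#' @export
setMethod("coilCount", "KSpaceVolume", function(x) dim(x@data)[3])

#' @rdname coilCount
#' @export
setMethod("coilCount", "CoilSensitivitySet", function(x) dim(x@maps)[3])

#' Number of slices in a k-space volume
#'
#' @param x a [KSpaceVolume-class].
#' @return integer slice count.
#' @export
setGeneric("sliceCount", function(x) standardGeneric("sliceCount"))

#' @rdname sliceCount
#' @export
setMethod("sliceCount", "KSpaceVolume", function(x) dim(x@data)[4])

#' Spatial shape (rows, columns)
#'
#' @param x a [KSpaceVolume-class], [CoilSensitivitySet-class] or
#'   [SamplingMask-class] (for masks only the column count is defined and a
#'   length-1 vector is returned).
#' @return integer vector.
#' @export
setGeneric("spatialShape", function(x) standardGeneric("spatialShape"))

#' @rdname spatialShape
#' @export
setMethod("spatialShape", "KSpaceVolume", function(x) dim(x@data)[1:2])

#' @rdname spatialShape
#' @export
setMethod("spatialShape", "CoilSensitivitySet", function(x) dim(x@maps)[1:2])

#' Raw k-space array
#'
#' @param x a [KSpaceVolume-class].
#' @return complex array `dim = c(rows, columns, coils, slices)`.
#' @export
setGeneric("kspaceData", function(x) standardGeneric("kspaceData"))

#' @rdname kspaceData
#' @export
setMethod("kspaceData", "KSpaceVolume", function(x) x@data)

#' Sensitivity map array
#'
#' @param x a [CoilSensitivitySet-class].
#' @return complex array `dim = c(rows, columns, coils)`.
#' @export
setGeneric("sensMaps", function(x) standardGeneric("sensMaps"))

#' @rdname sensMaps
#' @export
setMethod("sensMaps", "CoilSensitivitySet", function(x) x@maps)

#' Mask column indicator vector
#'
#' @param x a [SamplingMask-class].
#' @return integer 0/1 vector with one entry per k-space column.
#' @export
setGeneric("maskVector", function(x) standardGeneric("maskVector"))

#' @rdname maskVector
#' @export
setMethod("maskVector", "SamplingMask", function(x) x@columns)

#' Acceleration factor
#'
#' @param x a [SamplingMask-class] or [SyntheticSample-class].
#' @return integer acceleration factor.
#' @export
setGeneric("acceleration", function(x) standardGeneric("acceleration"))

#' @rdname acceleration
#' @export
setMethod("acceleration", "SamplingMask", function(x) x@acceleration)

#' @rdname acceleration
#' @export
setMethod("acceleration", "SyntheticSample", function(x) x@acceleration)

#' Ground-truth image of a synthetic sample
#'
#' @param x a [SyntheticSample-class].
#' @return numeric matrix.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SyntheticSample", function(x) x@groundTruth)

#' Model configuration
#'
#' @param x an [MLPEDModel-class].
#' @return the [NetworkConfig-class] the model was built with.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "MLPEDModel", function(x) x@config)

#' Model parameters
#'
#' @param x an [MLPEDModel-class].
#' @return named list of numeric parameter arrays.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname modelParams
#' @export
setMethod("modelParams", "MLPEDModel", function(x) x@params)

setMethod("show", "KSpaceVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("KSpaceVolume: %d slice(s), %d coil(s), %d x %d k-space\n",
              d[4], d[3], d[1], d[2]))
})

setMethod("show", "CoilSensitivitySet", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoilSensitivitySet: %d coil(s), %d x %d, %snormalized\n",
              d[3], d[1], d[2], if (object@normalized) "" else "not "))
})

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf(
    "SamplingMask: %s, %d-fold, %d/%d columns sampled (center fraction %.3g)\n",
    object@kind, object@acceleration, sum(object@columns),
    length(object@columns), object@centerFraction))
})

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig\n")
  cat("  channel schedule:", paste(object@channelSchedule, collapse = ", "),
      "\n")
  cat(sprintf("  %d encoder levels, %d pooling modules, zoom factor %d\n",
              object@encoderLevels, object@mlpLevels, object@zoomFactor))
  cat("  pooling kernels:", paste(object@rmpKernels, collapse = ", "), "\n")
  cat(sprintf("  dropout %.3g, LeakyReLU slope %.3g, %s norm\n",
              object@dropoutRate, object@leakySlope, object@normKind))
})

setMethod("show", "MLPEDModel", function(object) {
  cat(sprintf("MLPEDModel (%s mode): %s trainable parameters\n", object@mode,
              format(countTrainableParameters(object), big.mark = ",")))
  show(object@config)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d, %d ellipse(s), %s (speckle sd %.3g), seed %d\n",
              object@size[1], object@size[2], object@nEllipses,
              object@contrast, object@speckleSd, object@seed))
})

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf("SyntheticSample: %d x %d ground truth, %d coil(s), %d-fold %s mask\n",
              nrow(object@groundTruth), ncol(object@groundTruth),
              coilCount(object@kspace), object@acceleration,
              object@mask@kind))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: %d epoch(s), lr %.4g, %s, batch %d, seed %d\n",
              object@epochs, object@learningRate, object@optimizer,
              object@batchSize, object@seed))
})

setMethod("show", "VolumeRecord", function(object) {
  show(object@kspace)
  if (length(object@rssReference) > 0) {
    d <- dim(object@rssReference)
    cat(sprintf("  RSS reference: %d x %d x %d\n", d[1], d[2], d[3]))
  }
  if (length(object@attributes) > 0)
    cat("  attributes:", paste(names(object@attributes),
                               object@attributes, sep = "=", collapse = ", "),
        "\n")
})
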
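## fastMRI-dialect HDF5 persistence, run configuration, checkpoints, and
## structured logging.  On disk: complex64 dataset "kspace" of layout
## (slices, coils, rows, columns), optional float32 "reconstruction_rss" of
## layout (slices, rows, columns), string attributes on the root group.

#' Assemble a volume record
#'
#' @param kspace a [KSpaceVolume-class] or a complex 4-D array
#'   `(rows, columns, coils, slices)`.
#' @param rssReference optional numeric array `(rows, columns, slices)` (a
#'   matrix is treated as one slice).
#' @param attributes named character vector (e.g.
#'   `c(acquisition = "CORPD_FBK")`).
#' @return a [VolumeRecord-class].
#' @export
volumeRecord <- function(kspace, rssReference = NULL, attributes = character()) {
  if (!is(kspace, "KSpaceVolume"))
    kspace <- new("KSpaceVolume", data = kspace)
  if (is.null(rssReference)) {
    rssReference <- array(numeric(0), dim = c(0L, 0L, 0L))
  } else if (is.matrix(rssReference)) {
    rssReference <- array(rssReference, dim = c(dim(rssReference), 1L))
  }
  new("VolumeRecord", kspace = kspace, rssReference = rssReference,
      attributes = attributes)
}

#' Write a multi-coil volume to HDF5
#'
#' Values are stored as 32-bit floats (the dialect's native precision).
#'
#' @param record a [VolumeRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(record, path) {
  stopifnot(is(record, "VolumeRecord"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write to '", path, "': directory does not exist",
         call. = FALSE)
  attrs <- record@attributes
  if (length(attrs) > 0 && is.null(names(attrs)))
    stop("attributes must be named", call. = FALSE)
  .h5_write_volume(path.expand(path), record@kspace@data,
                   dim(record@kspace@data), as.numeric(record@rssReference),
                   dim(record@rssReference), attrs)
  invisible(path)
}

#' Read a multi-coil volume from HDF5
#'
#' @param path file with a complex dataset `"kspace"` of layout
#'   (slices, coils, rows, columns); a `"reconstruction_rss"` dataset and
#'   root string attributes are loaded when present.
#' @return a [VolumeRecord-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop("file '", path, "' does not exist", call. = FALSE)
  raw <- .h5_read_volume(path.expand(path))
  rss <- if (is.null(raw$rss)) array(numeric(0), dim = c(0L, 0L, 0L))
         else raw$rss
  attrs <- raw$attrs %||% character()
  new("VolumeRecord", kspace = new("KSpaceVolume", data = raw$kspace),
      rssReference = rss, attributes = attrs)
}

#' Save model weights and configuration to a checkpoint
#'
#' @param model an [MLPEDModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "MLPEDModel"))
  cfg <- model@config
  saveRDS(list(
    config = list(firstChannels = cfg@firstChannels,
                  encoderLevels = cfg@encoderLevels,
                  channelSchedule = cfg@channelSchedule,
                  zoomFactor = cfg@zoomFactor, rmpKernels = cfg@rmpKernels,
                  dropoutRate = cfg@dropoutRate, leakySlope = cfg@leakySlope,
                  normKind = cfg@normKind),
    params = model@params, mode = model@mode), path)
  invisible(path)
}

#' Load a model from a checkpoint
#'
#' @param path checkpoint written by [saveCheckpoint()].
#' @return an [MLPEDModel-class].
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(networkConfig, ck$config[c("firstChannels", "encoderLevels",
                                            "channelSchedule", "zoomFactor",
                                            "rmpKernels", "dropoutRate",
                                            "leakySlope", "normKind")])
  new("MLPEDModel", config = cfg, params = ck$params, mode = ck$mode)
}

runConfigDefaults <- function() {
  list(phantom = list(size = c(64L, 64L), nEllipses = 6L,
                      contrast = "pd_like", speckleSd = 0.2),
       simulate = list(nSamples = 16L, nCoils = 15L, accel = 4L,
                       noiseSd = 0.0, maskKind = "random"),
       network = list(firstChannels = 8L, encoderLevels = 5L,
                      zoomFactor = 2L, rmpKernels = c(2L, 3L, 5L, 6L),
                      dropoutRate = 0.0, leakySlope = 0.2),
       train = list(epochs = 10L, learningRate = 0.001, batchSize = 1L),
       seed = 1L)
}

#' Read a run configuration (YAML)
#'
#' Missing fields fall back to the documented defaults; unknown top-level
#' sections are rejected.
#'
#' @param path YAML file.
#' @return nested named list with sections `phantom`, `simulate`, `network`,
#'   `train`, and a top-level `seed`.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  defs <- runConfigDefaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad) > 0)
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(user)) {
    if (is.list(defs[[sec]])) {
      badf <- setdiff(names(user[[sec]]), names(defs[[sec]]))
      if (length(badf) > 0)
        stop("unknown field(s) in '", sec, "': ",
             paste(badf, collapse = ", "), call. = FALSE)
      defs[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      defs[[sec]] <- user[[sec]]
    }
  }
  defs
}

#' Write a run configuration (YAML)
#'
#' @param config nested list as returned by [readRunConfig()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

logEvent <- function(level, event, ..., logFile = NULL) {
  kv <- list(...)
  msg <- sprintf("%s %-5s %s%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 level, event,
                 if (length(kv) == 0) "" else paste0(" ",
                   paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
  cat(msg, "\n", file = stderr())
  if (!is.null(logFile)) cat(msg, "\n", file = logFile, append = TRUE)
  invisible(msg)
}
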
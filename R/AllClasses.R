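#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG recording in physical units
#' (microvolts), with channel labels, sampling rate and free-form metadata
#' (subject, intervention arm, timepoint, night, ...).
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot channelNames character vector of unique 10-20 (or referential
#'   PSG) channel labels, one per row of \code{data}.
#' @slot sfreq sampling frequency in Hz.
#' @slot meta named list of metadata.
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    data = "matrix",
    channelNames = "character",
    sfreq = "numeric",
    meta = "list"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(object@data))
    msg <- c(msg, "data must not contain NA/NaN")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "nrow(data) must equal length(channelNames)")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, sprintf("duplicate channel labels: %s",
      paste(unique(object@channelNames[duplicated(object@channelNames)]),
            collapse = ", ")))
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param channelNames character channel labels.
#' @param sfreq sampling frequency (Hz).
#' @param meta named list of metadata.
#' @return A \linkS4class{Recording}.
#' @examples
#' rec <- Recording(matrix(rnorm(2000), 2), c("Fz", "Cz"), 100)
#' nChannels(rec)
#' @export
Recording <- function(data, channelNames, sfreq, meta = list()) {
  dimnames(data) <- list(channelNames, NULL)
  new("Recording", data = data, channelNames = as.character(channelNames),
      sfreq = as.numeric(sfreq), meta = meta)
}

#' Fixed-length artifact-screened epochs
#'
#' Consecutive non-overlapping fixed-length segments cut from a
#' \linkS4class{Recording}, with per-channel amplitude-artifact bookkeeping
#' and the kept/rejected partition of segment indices. All segments are
#' retained in the array; analysis stages consume only \code{keptIndices}.
#'
#' @slot epochs numeric array, epoch x channel x sample (microvolts).
#' @slot epochLength segment length in seconds.
#' @slot sfreq sampling frequency in Hz.
#' @slot channelNames labels of retained channels.
#' @slot keptIndices,rejectedIndices integer indices into the original
#'   consecutive segmentation; a disjoint partition of all segments.
#' @slot channelArtifacts logical matrix, segment x channel: TRUE where the
#'   channel exceeds the amplitude threshold within the segment.
#' @slot threshold absolute-amplitude rejection threshold in microvolts.
#' @slot excludedChannels labels of channels dropped for excessive artifact
#'   load.
#' @slot meta named list of metadata.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    epochLength = "numeric",
    sfreq = "numeric",
    channelNames = "character",
    keptIndices = "integer",
    rejectedIndices = "integer",
    channelArtifacts = "matrix",
    threshold = "numeric",
    excludedChannels = "character",
    meta = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (d[2] != length(object@channelNames))
      msg <- c(msg, "dim(epochs)[2] must equal length(channelNames)")
    all_idx <- sort(c(object@keptIndices, object@rejectedIndices))
    if (!identical(all_idx, seq_len(d[1])))
      msg <- c(msg,
        "keptIndices and rejectedIndices must partition all segments")
  }
  if (length(intersect(object@keptIndices, object@rejectedIndices)))
    msg <- c(msg, "keptIndices and rejectedIndices must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Per-channel, per-band spectral power
#'
#' Mean power spectral density within each frequency band (microV^2/Hz) for
#' each channel of one recording, timepoint or sleep-stage context.
#'
#' @slot values numeric matrix, channel x band, in microV^2/Hz.
#' @slot bands data.frame of band definitions (name, flo, fhi).
#' @slot nEpochsUsed number of artifact-free epochs averaged.
#' @slot freqResolution frequency grid spacing in Hz.
#' @slot meta named list (subject, arm, timepoint or stage, ...).
#'
#' @exportClass BandPowerTable
setClass("BandPowerTable",
  representation(
    values = "matrix",
    bands = "data.frame",
    nEpochsUsed = "integer",
    freqResolution = "numeric",
    meta = "list"
  )
)

setValidity("BandPowerTable", function(object) {
  msg <- character()
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "band power values must be non-negative")
  if (object@nEpochsUsed < 1L)
    msg <- c(msg, "nEpochsUsed must be >= 1")
  if (ncol(object@values) != nrow(object@bands))
    msg <- c(msg, "one value column per band required")
  if (length(msg)) msg else TRUE
})

#' Phase-locking-value adjacency matrix
#'
#' Symmetric matrix of phase-locking values between all channel pairs in one
#' frequency band, unit diagonal, entries in [0, 1].
#'
#' @slot values numeric matrix, channels x channels.
#' @slot band list with elements \code{name}, \code{flo}, \code{fhi}.
#' @slot nEpochsUsed number of epochs averaged.
#' @slot channelNames channel labels.
#' @slot meta named list of metadata.
#'
#' @exportClass PLVMatrix
setClass("PLVMatrix",
  representation(
    values = "matrix",
    band = "list",
    nEpochsUsed = "integer",
    channelNames = "character",
    meta = "list"
  )
)

setValidity("PLVMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v))
    msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@channelNames))
    msg <- c(msg, "one channel label per row required")
  if (any(v < -1e-9 | v > 1 + 1e-9))
    msg <- c(msg, "PLV entries must lie in [0, 1]")
  if (max(abs(v - t(v))) > 1e-9)
    msg <- c(msg, "values must be symmetric")
  if (any(abs(diag(v) - 1) > 1e-9))
    msg <- c(msg, "diagonal must equal 1")
  if (length(msg)) msg else TRUE
})

#' Sleep-stage hypnogram
#'
#' Sequence of 30-s AASM sleep-stage labels (W, N1, N2, N3, R) with
#' lights-off/lights-on epoch indices delimiting time in bed.
#'
#' @slot stages character vector of stage labels.
#' @slot epochLength epoch length in seconds (AASM convention: 30).
#' @slot lightsOff,lightsOn epoch indices (inclusive) of the in-bed span.
#'
#' @exportClass Hypnogram
setClass("Hypnogram",
  representation(
    stages = "character",
    epochLength = "numeric",
    lightsOff = "integer",
    lightsOn = "integer"
  )
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (!length(object@stages))
    msg <- c(msg, "stages must be non-empty")
  bad <- setdiff(unique(object@stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad))
    msg <- c(msg, sprintf("invalid stage labels: %s",
                          paste(bad, collapse = ", ")))
  if (object@lightsOff < 1L || object@lightsOn > length(object@stages) ||
      object@lightsOff >= object@lightsOn)
    msg <- c(msg, "need 1 <= lightsOff < lightsOn <= length(stages)")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector over W, N1, N2, N3, R.
#' @param epochLength epoch length in seconds (default 30).
#' @param lightsOff,lightsOn epoch indices bounding time in bed; default the
#'   whole sequence.
#' @return A \linkS4class{Hypnogram}.
#' @export
Hypnogram <- function(stages, epochLength = 30,
                      lightsOff = 1L, lightsOn = length(stages)) {
  new("Hypnogram", stages = as.character(stages),
      epochLength = as.numeric(epochLength),
      lightsOff = as.integer(lightsOff), lightsOn = as.integer(lightsOn))
}

#' NREM-REM sleep cycles
#'
#' Ordered, non-overlapping NREM-REM cycles detected on a hypnogram by the
#' Feinberg-Floyd criteria.
#'
#' @slot cycles data.frame with epoch-index columns \code{nremStart},
#'   \code{nremEnd}, \code{remStart}, \code{remEnd} (the REM columns are NA
#'   for an allowed incomplete final cycle).
#' @slot ruleParams named list of the detection parameters used.
#'
#' @exportClass SleepCycleSet
setClass("SleepCycleSet",
  representation(cycles = "data.frame", ruleParams = "list")
)

setValidity("SleepCycleSet", function(object) {
  cyc <- object@cycles
  msg <- character()
  if (nrow(cyc) > 1) {
    ends <- ifelse(is.na(cyc$remEnd), cyc$nremEnd, cyc$remEnd)
    if (any(cyc$nremStart[-1] <= ends[-nrow(cyc)]))
      msg <- c(msg, "cycles must be ordered and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @rdname Recording
#' @param object,x a Recording or EpochSet.
#' @export
setGeneric("recData", function(object) standardGeneric("recData"))
#' @rdname Recording
#' @export
setMethod("recData", "Recording", function(object) object@data)

#' @rdname Recording
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname Recording
#' @export
setMethod("channelNames", "Recording", function(object) object@channelNames)
#' @rdname Recording
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
#' @rdname Recording
#' @export
setMethod("channelNames", "PLVMatrix", function(object) object@channelNames)

#' @rdname Recording
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname Recording
#' @export
setMethod("samplingRate", "Recording", function(object) object@sfreq)
#' @rdname Recording
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@sfreq)

#' @rdname Recording
#' @export
nChannels <- function(x) length(channelNames(x))

#' @rdname Recording
#' @export
setGeneric("recDuration", function(object) standardGeneric("recDuration"))
#' @rdname Recording
#' @export
setMethod("recDuration", "Recording",
          function(object) ncol(object@data) / object@sfreq)

#' @rdname EpochSet
#' @param object an EpochSet.
#' @export
setGeneric("keptIndices", function(object) standardGeneric("keptIndices"))
#' @rdname EpochSet
#' @export
setMethod("keptIndices", "EpochSet", function(object) object@keptIndices)

#' @rdname EpochSet
#' @export
setGeneric("rejectedIndices",
           function(object) standardGeneric("rejectedIndices"))
#' @rdname EpochSet
#' @export
setMethod("rejectedIndices", "EpochSet",
          function(object) object@rejectedIndices)

#' @rdname EpochSet
#' @export
setGeneric("excludedChannels",
           function(object) standardGeneric("excludedChannels"))
#' @rdname EpochSet
#' @export
setMethod("excludedChannels", "EpochSet",
          function(object) object@excludedChannels)

#' @rdname BandPowerTable
#' @param object a BandPowerTable or PLVMatrix.
#' @export
setGeneric("bandValues", function(object) standardGeneric("bandValues"))
#' @rdname BandPowerTable
#' @export
setMethod("bandValues", "BandPowerTable", function(object) object@values)

#' @rdname PLVMatrix
#' @param object a PLVMatrix.
#' @export
setGeneric("plvValues", function(object) standardGeneric("plvValues"))
#' @rdname PLVMatrix
#' @export
setMethod("plvValues", "PLVMatrix", function(object) object@values)

#' @rdname Hypnogram
#' @param object a Hypnogram.
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))
#' @rdname Hypnogram
#' @export
setMethod("stages", "Hypnogram", function(object) object@stages)

#' @rdname SleepCycleSet
#' @param object a SleepCycleSet.
#' @export
setGeneric("cycles", function(object) standardGeneric("cycles"))
#' @rdname SleepCycleSet
#' @export
setMethod("cycles", "SleepCycleSet", function(object) object@cycles)

# ---- show methods ----

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sfreq,
              recDuration(object)))
  cat("  channels:", paste(utils::head(object@channelNames, 8),
                           collapse = ", "),
      if (length(object@channelNames) > 8) "..." else "", "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta),
                         vapply(object@meta, function(v)
                           paste(format(v), collapse = "/"), ""),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet: %d x %g s epochs (%d kept, %d rejected) x %d channels\n",
    d[1], object@epochLength, length(object@keptIndices),
    length(object@rejectedIndices), d[2]))
  if (length(object@excludedChannels))
    cat("  excluded channels:",
        paste(object@excludedChannels, collapse = ", "), "\n")
})

setMethod("show", "BandPowerTable", function(object) {
  cat(sprintf("BandPowerTable: %d channels x %d bands (%d epochs, df=%g Hz)\n",
              nrow(object@values), ncol(object@values), object@nEpochsUsed,
              object@freqResolution))
  print(round(object@values, 4))
})

setMethod("show", "PLVMatrix", function(object) {
  cat(sprintf("PLVMatrix: %d x %d, band %s [%g, %g) Hz, %d epochs\n",
              nrow(object@values), ncol(object@values),
              object@band$name, object@band$flo, object@band$fhi,
              object@nEpochsUsed))
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("  off-diagonal PLV: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, c("W", "N1", "N2", "N3", "R")))
  cat(sprintf("Hypnogram: %d x %g s epochs (%.1f min)\n",
              length(object@stages), object@epochLength,
              length(object@stages) * object@epochLength / 60))
  cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

setMethod("show", "SleepCycleSet", function(object) {
  cat(sprintf("SleepCycleSet: %d cycle(s)\n", nrow(object@cycles)))
  if (nrow(object@cycles)) print(object@cycles)
})
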
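#' Select and reorder channels
#'
#' Returns a \linkS4class{Recording} restricted to \code{subset}, in the
#' requested order. Used to sparsify dense montages before connectivity
#' analysis (volume-conduction mitigation by electrode sparsification).
#'
#' @param rec a \linkS4class{Recording}.
#' @param subset character vector of channel labels to keep, in the desired
#'   output order.
#' @return A \linkS4class{Recording} with channels in \code{subset} order.
#' @export
selectChannels <- function(rec, subset) {
  stopifnot(is(rec, "Recording"))
  missing <- setdiff(subset, rec@channelNames)
  if (length(missing))
    stop(sprintf("channel label(s) not present in recording: %s",
                 paste(missing, collapse = ", ")))
  idx <- match(subset, rec@channelNames)
  Recording(rec@data[idx, , drop = FALSE], subset, rec@sfreq, rec@meta)
}

#' The 21-channel wake analysis montage
#'
#' The 10-20 subset used for wake spectral and connectivity analysis.
#'
#' @return character vector of 21 channel labels.
#' @export
wakeMontage <- function() {
  c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4",
    "P3", "Pz", "P4", "O1", "Oz", "O2", "F7", "F8", "T7", "T8",
    "P7", "P8")
}

#' Common-average reference
#'
#' Subtracts the instantaneous mean across the retained channels from every
#' channel, so that each output sample has zero mean across channels.
#'
#' @param rec a \linkS4class{Recording}.
#' @return The re-referenced \linkS4class{Recording}.
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "Recording"))
  d <- rec@data
  d <- sweep(d, 2, colMeans(d))
  Recording(d, rec@channelNames, rec@sfreq, rec@meta)
}

#' Standard preprocessing chain for continuous EEG
#'
#' Common-average reference, then 1-60 Hz band-pass (4th-order Butterworth),
#' then 50 Hz notch (2nd-order IIR, quality 30), each applied
#' forward-backward for zero net phase shift. The same chain serves wake
#' EEG (1000 Hz) and sleep PSG (512 Hz); only the segmentation length
#' differs downstream.
#'
#' @param rec a \linkS4class{Recording}; sampling rate must exceed twice
#'   the upper band edge.
#' @param lowCut,highCut band-pass edges in Hz (defaults 1 and 60).
#' @param notchFreq line frequency to notch out in Hz (default 50); NULL
#'   disables the notch.
#' @param notchQ notch quality factor (default 30).
#' @param reference apply the common-average reference first (default TRUE).
#' @return The preprocessed \linkS4class{Recording}.
#' @export
preprocessWake <- function(rec, lowCut = 1, highCut = 60,
                           notchFreq = 50, notchQ = 30, reference = TRUE) {
  stopifnot(is(rec, "Recording"))
  nyq <- rec@sfreq / 2
  if (highCut >= nyq)
    stop(sprintf(
      "sampling rate %g Hz too low: Nyquist frequency %g Hz must exceed the %g Hz band edge",
      rec@sfreq, nyq, highCut))
  if (reference) rec <- commonAverageReference(rec)
  bp <- designBandpass(lowCut, highCut, rec@sfreq)
  d <- filtfiltRows(bp, rec@data)
  if (!is.null(notchFreq)) {
    nf <- designNotch(notchFreq, rec@sfreq, notchQ)
    d <- filtfiltRows(nf, d)
  }
  Recording(d, rec@channelNames, rec@sfreq, rec@meta)
}

#' @rdname preprocessWake
#' @export
preprocessSleep <- preprocessWake

#' Segment a recording and reject amplitude artifacts
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' \code{epochLength} seconds (a trailing partial segment is discarded,
#' never padded) and rejects every epoch in which any retained channel
#' strictly exceeds \code{threshold} microvolts in absolute amplitude at
#' any sample. Per-channel threshold crossings are kept per segment so that
#' \code{\link{excludeBadChannels}} can apply the channel-level artifact
#' rule afterwards.
#'
#' @param rec a \linkS4class{Recording} of duration >= epochLength.
#' @param epochLength segment length in seconds (5 for wake, 30 for sleep).
#' @param threshold absolute-amplitude artifact threshold in microvolts
#'   (default 100; the rule is strict: |x| > threshold).
#' @return An \linkS4class{EpochSet}.
#' @export
segmentAndReject <- function(rec, epochLength, threshold = 100) {
  stopifnot(is(rec, "Recording"))
  spe <- round(epochLength * rec@sfreq)
  nseg <- floor(ncol(rec@data) / spe)
  if (nseg < 1L)
    stop(sprintf("recording duration %.2f s shorter than epoch length %g s",
                 recDuration(rec), epochLength))
  nch <- nrow(rec@data)
  ep <- array(NA_real_, c(nseg, nch, spe))
  chart <- matrix(FALSE, nseg, nch,
                  dimnames = list(NULL, rec@channelNames))
  for (s in seq_len(nseg)) {
    seg <- rec@data[, ((s - 1) * spe + 1):(s * spe), drop = FALSE]
    ep[s, , ] <- seg
    chart[s, ] <- apply(abs(seg) > threshold, 1, any)
  }
  rejected <- which(rowSums(chart) > 0)
  kept <- setdiff(seq_len(nseg), rejected)
  if (length(kept) == 0L)
    warning("no analyzable data: every epoch exceeds the amplitude threshold",
            call. = FALSE)
  new("EpochSet", epochs = ep, epochLength = as.numeric(epochLength),
      sfreq = rec@sfreq, channelNames = rec@channelNames,
      keptIndices = as.integer(kept), rejectedIndices = as.integer(rejected),
      channelArtifacts = chart, threshold = as.numeric(threshold),
      excludedChannels = character(), meta = rec@meta)
}

#' Exclude channels with excessive artifact load
#'
#' Drops every channel whose fraction of artifact-bearing segments is
#' strictly greater than \code{maxArtifactFraction} (default 0.5, the
#' "more than 50\% of the recording time" rule), then recomputes the epoch
#' kept/rejected partition on the retained channels only — epochs bad only
#' on an excluded channel become kept.
#'
#' @param es an \linkS4class{EpochSet} from \code{\link{segmentAndReject}}.
#' @param maxArtifactFraction maximum tolerated artifact-segment fraction
#'   per channel (strict inequality).
#' @return An \linkS4class{EpochSet} on the retained channels.
#' @export
excludeBadChannels <- function(es, maxArtifactFraction = 0.5) {
  stopifnot(is(es, "EpochSet"))
  frac <- colMeans(es@channelArtifacts)
  drop <- which(frac > maxArtifactFraction)
  if (length(drop) == ncol(es@channelArtifacts))
    stopNoData("all channels exceed the artifact-fraction limit")
  if (length(drop) == 0L) return(es)
  keep <- setdiff(seq_along(es@channelNames), drop)
  chart <- es@channelArtifacts[, keep, drop = FALSE]
  rejected <- which(rowSums(chart) > 0)
  kept <- setdiff(seq_len(nrow(chart)), rejected)
  new("EpochSet", epochs = es@epochs[, keep, , drop = FALSE],
      epochLength = es@epochLength, sfreq = es@sfreq,
      channelNames = es@channelNames[keep],
      keptIndices = as.integer(kept), rejectedIndices = as.integer(rejected),
      channelArtifacts = chart, threshold = es@threshold,
      excludedChannels = c(es@excludedChannels, es@channelNames[drop]),
      meta = es@meta)
}

#' Keep only a subset of epochs in an EpochSet
#'
#' Restricts the segment array to \code{indices} (in the original
#' segmentation numbering), preserving artifact bookkeeping. Used to pull
#' the epochs of one sleep stage or one sleep cycle out of a night.
#'
#' @param es an \linkS4class{EpochSet}.
#' @param indices segment indices to retain.
#' @return An \linkS4class{EpochSet} containing only those segments
#'   (renumbered consecutively).
#' @export
subsetEpochs <- function(es, indices) {
  stopifnot(is(es, "EpochSet"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > dim(es@epochs)[1]))
    stop("epoch indices out of range")
  chart <- es@channelArtifacts[indices, , drop = FALSE]
  rejected <- which(rowSums(chart) > 0)
  kept <- setdiff(seq_along(indices), rejected)
  new("EpochSet", epochs = es@epochs[indices, , , drop = FALSE],
      epochLength = es@epochLength, sfreq = es@sfreq,
      channelNames = es@channelNames,
      keptIndices = as.integer(kept), rejectedIndices = as.integer(rejected),
      channelArtifacts = chart, threshold = es@threshold,
      excludedChannels = es@excludedChannels, meta = es@meta)
}
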
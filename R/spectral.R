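#' Default EEG frequency bands
#'
#' Canonical band edges used throughout the package: delta [1, 4), theta
#' [5, 8), alpha [8, 13), beta [13, 30), gamma [30, 60) Hz. Band membership
#' of a frequency bin is half-open, \code{flo <= f < fhi}, so the shared
#' 8 Hz edge belongs to alpha and the [4, 5) Hz gap between delta and theta
#' belongs to no band. The theta lower edge is configurable via
#' \code{thetaLow} for analyses that prefer a contiguous 4 Hz boundary.
#'
#' @param thetaLow lower edge of the theta band in Hz (default 5).
#' @return data.frame with columns \code{name}, \code{flo}, \code{fhi}.
#' @examples
#' eegBands()
#' @export
eegBands <- function(thetaLow = 5) {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    flo  = c(1, thetaLow, 8, 13, 30),
    fhi  = c(4, 8, 13, 30, 60),
    stringsAsFactors = FALSE
  )
}

#' Welch power spectral density of an epoch set
#'
#' Averaged modified periodogram over the kept (artifact-free) epochs: one
#' Hamming-windowed periodogram per epoch, the whole epoch as a single
#' segment (no sub-segmentation, no overlap), averaged across epochs. The
#' density normalization is such that the integral of the PSD of
#' unit-variance white noise over [0, Nyquist] equals 1 in expectation;
#' one-sided, with interior bins doubled. Frequency resolution is
#' 1/epochLength.
#'
#' @param es an \linkS4class{EpochSet}.
#' @return list with \code{freqs} (Hz) and \code{psd} (channels x
#'   frequencies matrix, microV^2/Hz), plus \code{nEpochsUsed}.
#' @export
welchPsd <- function(es) {
  stopifnot(is(es, "EpochSet"))
  kept <- es@keptIndices
  if (length(kept) == 0L)
    stopNoData("zero kept epochs for Welch PSD")
  d <- dim(es@epochs)
  n <- d[3]
  fs <- es@sfreq
  w <- hammingWindow(n)
  U <- sum(w^2)
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1) * fs / n
  acc <- matrix(0, d[2], nf)
  for (e in kept) {
    seg <- t(es@epochs[e, , , drop = FALSE][1, , ]) * w   # samples x channels
    if (d[2] == 1L) seg <- matrix(es@epochs[e, 1, ] * w, ncol = 1)
    X <- stats::mvfft(seg)
    P <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (fs * U)
    # one-sided: double everything except DC and (for even n) Nyquist
    dbl <- rep(2, nf); dbl[1] <- 1
    if (n %% 2 == 0) dbl[nf] <- 1
    acc <- acc + t(P * dbl)
  }
  list(freqs = freqs, psd = acc / length(kept),
       nEpochsUsed = length(kept), freqResolution = fs / n,
       channelNames = es@channelNames)
}

#' Band power from a PSD
#'
#' Mean PSD within each band, using the half-open convention
#' \code{flo <= f < fhi}. Units are microV^2/Hz (mean density in band, not
#' the integral).
#'
#' @param freqs frequency grid (Hz), or the list returned by
#'   \code{\link{welchPsd}} (in which case \code{psd} is taken from it).
#' @param psd channels x frequencies PSD matrix.
#' @param bands band definition data.frame, see \code{\link{eegBands}}.
#' @param channelNames optional channel labels for the rows of \code{psd}.
#' @param meta metadata list attached to the result.
#' @param nEpochsUsed number of epochs behind the PSD (bookkeeping).
#' @return A \linkS4class{BandPowerTable}.
#' @export
bandPower <- function(freqs, psd = NULL, bands = eegBands(),
                      channelNames = NULL, meta = list(),
                      nEpochsUsed = NA_integer_) {
  if (is.list(freqs) && !is.null(freqs$psd)) {
    w <- freqs
    freqs <- w$freqs; psd <- w$psd
    if (is.null(channelNames)) channelNames <- w$channelNames
    if (is.na(nEpochsUsed)) nEpochsUsed <- w$nEpochsUsed
    freqRes <- w$freqResolution
  } else {
    freqRes <- if (length(freqs) > 1) diff(freqs[1:2]) else NA_real_
  }
  if (is.na(nEpochsUsed)) nEpochsUsed <- 1L
  vals <- matrix(NA_real_, nrow(psd), nrow(bands),
                 dimnames = list(channelNames, bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$flo[b] & freqs < bands$fhi[b]
    if (!any(sel))
      stop(sprintf(
        "band %s [%g, %g) contains no frequency bin at resolution %g Hz",
        bands$name[b], bands$flo[b], bands$fhi[b], freqRes))
    vals[, b] <- rowMeans(psd[, sel, drop = FALSE])
  }
  new("BandPowerTable", values = vals, bands = bands,
      nEpochsUsed = as.integer(nEpochsUsed),
      freqResolution = as.numeric(freqRes), meta = meta)
}

#' Post-minus-baseline band-power change with cross-subject z-scores
#'
#' For each subject, the band power at the requested channel at the final
#' timepoint minus the baseline timepoint; z-scores are standardized across
#' subjects within each band using the population (n-denominator) standard
#' deviation, so within each band the z-scores have mean 0 and SD 1.
#'
#' @param baseline named list (by subject) of \linkS4class{BandPowerTable}
#'   at the baseline timepoint.
#' @param post named list (by subject) of tables at the post timepoint; must
#'   cover the same subjects.
#' @param channel electrode label at which the change is computed (the
#'   stimulation-target electrode, e.g. "F4").
#' @return data.frame with columns subject, band, psdChange, zscore.
#'   Bands with zero between-subject SD get NA z-scores and a warning
#'   (degenerate-SD condition).
#' @export
deltaPsdZscores <- function(baseline, post, channel) {
  subjects <- names(baseline)
  missing_post <- setdiff(subjects, names(post))
  missing_base <- setdiff(names(post), subjects)
  if (length(missing_post) || length(missing_base))
    stop(sprintf("missing timepoint tables for subject(s): %s",
                 paste(unique(c(missing_post, missing_base)),
                       collapse = ", ")))
  bands <- baseline[[1]]@bands$name
  out <- do.call(rbind, lapply(subjects, function(s) {
    b0 <- bandValues(baseline[[s]]); b1 <- bandValues(post[[s]])
    if (!channel %in% rownames(b0) || !channel %in% rownames(b1))
      stop(sprintf("channel %s absent for subject %s", channel, s))
    data.frame(subject = s, band = bands,
               psdChange = as.numeric(b1[channel, bands] - b0[channel, bands]),
               stringsAsFactors = FALSE)
  }))
  out$zscore <- NA_real_
  for (b in bands) {
    i <- out$band == b
    x <- out$psdChange[i]
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))  # population SD
    if (sdp == 0) {
      warning(sprintf(
        "degenerate SD: zero between-subject variance in band %s; z-scores set to NA", b))
    } else {
      out$zscore[i] <- (x - mu) / sdp
    }
  }
  rownames(out) <- NULL
  out
}

#' Tidy long-format view of a BandPowerTable
#'
#' @param bp a \linkS4class{BandPowerTable}.
#' @return data.frame (channel, band, value) plus any scalar metadata.
#' @export
bandPowerTable <- function(bp) {
  v <- bandValues(bp)
  out <- data.frame(
    channel = rep(rownames(v), ncol(v)),
    band = rep(colnames(v), each = nrow(v)),
    value = as.numeric(v),
    stringsAsFactors = FALSE
  )
  for (nm in names(bp@meta))
    if (length(bp@meta[[nm]]) == 1L) out[[nm]] <- bp@meta[[nm]]
  out
}
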
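#' Instantaneous phase of band-limited epochs
#'
#' Band-pass filters every kept epoch to the band edges (4th-order
#' Butterworth, forward-backward, zero net phase) and extracts the
#' analytic-signal phase via the Hilbert transform. A guard fraction of
#' samples at both epoch ends is flagged for exclusion from subsequent
#' time averages, since both the filter and the transform distort epoch
#' edges.
#'
#' @param es an \linkS4class{EpochSet}.
#' @param band one row of a band definition data.frame (or a list with
#'   \code{name}, \code{flo}, \code{fhi}).
#' @param guardFraction fraction of samples flagged at each epoch end
#'   (default 0.1).
#' @return A list of class \code{phaseArray}: \code{phase} (kept-epoch x
#'   channel x sample array, radians), \code{interior} (sample indices used
#'   in averaging), \code{band}, \code{channelNames}, \code{sfreq}.
#' @export
instantaneousPhase <- function(es, band, guardFraction = 0.1) {
  stopifnot(is(es, "EpochSet"))
  band <- as.list(band)
  nyq <- es@sfreq / 2
  if (band$flo <= 0 || band$fhi >= nyq)
    stop(sprintf("band [%g, %g) Hz outside (0, Nyquist=%g) at %g Hz sampling",
                 band$flo, band$fhi, nyq, es@sfreq))
  kept <- es@keptIndices
  if (length(kept) == 0L)
    stopNoData("zero kept epochs for phase extraction")
  d <- dim(es@epochs)
  bp <- designBandpass(band$flo, band$fhi, es@sfreq)
  ph <- array(NA_real_, c(length(kept), d[2], d[3]))
  for (i in seq_along(kept)) {
    for (ch in seq_len(d[2])) {
      x <- zeroPhaseFilter(bp, es@epochs[kept[i], ch, ])
      ph[i, ch, ] <- Arg(analyticSignal(x))
    }
  }
  g <- max(0L, floor(guardFraction * d[3]))
  interior <- seq.int(g + 1L, d[3] - g)
  phaseArray(ph, interior, band, es@channelNames, es@sfreq)
}

#' Construct a phaseArray
#'
#' Low-level constructor for the phase container consumed by
#' \code{\link{plvMatrix}}; normally produced by
#' \code{\link{instantaneousPhase}}, but it can be built directly from raw
#' phase traces (e.g. for calibration against analytic nulls).
#'
#' @param phase epoch x channel x sample array of phases (radians).
#' @param interior sample indices included in time averages.
#' @param band list with \code{name}, \code{flo}, \code{fhi} (may be empty).
#' @param channelNames channel labels.
#' @param sfreq sampling rate in Hz (bookkeeping only).
#' @return list of class \code{phaseArray}.
#' @export
phaseArray <- function(phase, interior = seq_len(dim(phase)[3]),
                       band = list(name = "", flo = NA, fhi = NA),
                       channelNames = paste0("ch", seq_len(dim(phase)[2])),
                       sfreq = NA_real_) {
  structure(list(phase = phase, interior = as.integer(interior),
                 band = as.list(band), channelNames = channelNames,
                 sfreq = sfreq),
            class = "phaseArray")
}

#' Phase-locking-value adjacency matrix
#'
#' For every channel pair (j, k) and epoch, the modulus of the time average
#' over interior samples of exp(i (phi_j - phi_k)); the matrix entry is the
#' mean of these per-epoch moduli across epochs (mean of moduli, not
#' modulus of the grand mean). Symmetric with unit diagonal by
#' construction; entries in [0, 1]. PLV is invariant to channel amplitude
#' and to any constant phase lag.
#'
#' @param ph a \code{phaseArray} from \code{\link{instantaneousPhase}} or
#'   \code{\link{phaseArray}}.
#' @param meta metadata list attached to the result.
#' @return A \linkS4class{PLVMatrix}.
#' @export
plvMatrix <- function(ph, meta = list()) {
  stopifnot(inherits(ph, "phaseArray"))
  d <- dim(ph$phase)
  if (d[1] == 0L)
    stopNoData("zero epochs for PLV")
  Tn <- length(ph$interior)
  acc <- matrix(0, d[2], d[2])
  for (e in seq_len(d[1])) {
    Z <- exp(1i * ph$phase[e, , ph$interior, drop = FALSE][1, , ])
    if (d[2] == 1L) Z <- matrix(exp(1i * ph$phase[e, 1, ph$interior]), 1)
    M <- Z %*% Conj(t(Z)) / Tn
    acc <- acc + Mod(M)
  }
  v <- acc / d[1]
  v <- (v + t(v)) / 2
  v <- pmin(pmax(v, 0), 1)
  diag(v) <- 1
  dimnames(v) <- list(ph$channelNames, ph$channelNames)
  new("PLVMatrix", values = v, band = ph$band,
      nEpochsUsed = as.integer(d[1]), channelNames = ph$channelNames,
      meta = meta)
}

#' Band-specific PLV matrix of an epoch set
#'
#' Convenience chain of \code{\link{instantaneousPhase}} and
#' \code{\link{plvMatrix}}.
#'
#' @inheritParams instantaneousPhase
#' @param meta metadata list attached to the result.
#' @return A \linkS4class{PLVMatrix}.
#' @export
phaseLockingValue <- function(es, band, guardFraction = 0.1, meta = list()) {
  plvMatrix(instantaneousPhase(es, band, guardFraction), meta = meta)
}

#' Long-form edge table of a PLV matrix
#'
#' @param plv a \linkS4class{PLVMatrix}.
#' @return data.frame (chanA, chanB, band, plv) over the upper triangle.
#' @export
plvEdgeTable <- function(plv) {
  v <- plvValues(plv)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  data.frame(
    chanA = plv@channelNames[ut[, 1]],
    chanB = plv@channelNames[ut[, 2]],
    band = plv@band$name,
    plv = v[ut],
    stringsAsFactors = FALSE
  )
}
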
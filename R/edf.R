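# Minimal European Data Format (EDF) reader/writer for continuous
# multichannel recordings: 16-bit little-endian samples, one fixed-length
# data-record duration, physical units microvolts. Covers the subset of
# the format the package produces and consumes (no annotations, no
# discontinuous records).

edfPad <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a Recording as EDF
#'
#' 16-bit EDF with physical units microvolts, one-second data records.
#' The physical range is the recording's symmetric amplitude range, so
#' round-trip error is bounded by the 16-bit quantization step.
#'
#' @param rec a \linkS4class{Recording}; \code{sfreq} must be an integer
#'   number of samples per second.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdf <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@sfreq
  if (fs != round(fs))
    stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec@data)
  spr <- as.integer(fs)                      # samples per 1-s record
  nrec <- floor(ncol(rec@data) / spr)
  if (nrec < 1) stop("recording shorter than one EDF data record (1 s)")
  physMax <- max(1e-6, max(abs(rec@data)))
  digMax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * ns
  writeChar(paste0(
    edfPad("0", 8),
    edfPad("X X X X", 80),                   # local patient id
    edfPad("Startdate X X X X", 80),         # local recording id
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(hdrBytes, 8), edfPad("", 44),
    edfPad(nrec, 8), edfPad(1, 8), edfPad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edfPad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec@channelNames, 16)
  field(rep("", ns), 80)                     # transducer
  field(rep("uV", ns), 8)                    # physical dimension
  field(rep(sprintf("%.6g", -physMax), ns), 8)
  field(rep(sprintf("%.6g", physMax), ns), 8)
  field(rep(-digMax, ns), 8)
  field(rep(digMax, ns), 8)
  field(rep("", ns), 80)                     # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                     # reserved
  scale <- digMax / physMax
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round(rec@data[, idx, drop = FALSE] * scale)
    dig <- pmin(pmax(dig, -digMax), digMax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the subset of EDF written by \code{\link{writeEdf}} and by
#' standard continuous-EEG exporters: equal sampling rate across EEG
#' signals, 16-bit samples. Physical units must resolve to microvolts
#' ("uV"); millivolt signals are converted. Channel labels are normalized
#' to 10-20 names.
#'
#' @param path EDF file path.
#' @param meta metadata list attached to the Recording.
#' @return A \linkS4class{Recording} in microvolts.
#' @export
readEdf <- function(path, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  version <- rd(8)
  if (version != "0")
    stop(sprintf("unparseable EDF file (bad version field): %s", path))
  invisible(rd(80)); invisible(rd(80))
  invisible(rd(8)); invisible(rd(8))
  invisible(rd(8))                            # header bytes
  invisible(rd(44))
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(nrec) || is.na(ns) || ns < 1)
    stop(sprintf("unparseable EDF header: %s", path))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- normalizeChannelLabel(rdv(16))
  invisible(rdv(80))
  dims <- rdv(8)
  physMin <- as.numeric(rdv(8)); physMax <- as.numeric(rdv(8))
  digMin <- as.numeric(rdv(8)); digMax <- as.numeric(rdv(8))
  invisible(rdv(80))
  spr <- as.integer(rdv(8))
  invisible(rdv(32))
  if (anyDuplicated(labels))
    stop(sprintf("duplicate channel label(s): %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  unitScale <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1000,
           stop(sprintf("unknown physical unit '%s': cannot resolve to microvolts", d)))
  }, numeric(1))
  if (length(unique(spr)) != 1)
    stop("EDF reader requires a common sampling rate across signals")
  sfreq <- spr[1] / recDur
  data <- matrix(0, ns, nrec * spr[1])
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * spr[s] + 1):(r * spr[s])
      data[s, idx] <- (raw - digMin[s]) * gain[s] + physMin[s]
    }
  }
  data <- data * unitScale
  Recording(data, labels, sfreq, meta)
}
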
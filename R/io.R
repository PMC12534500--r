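# Readers and writers for the supported on-disk formats: delimited
# numeric matrices with a channel-name header, EDF (see edf.R), 2-column
# hypnogram text, YAML simulation/pipeline configs, JSON ground truth.

# Canonical capitalization of 10-20 labels plus stripping of common EDF
# label decorations ("EEG " prefix, "-REF"/"-LE"/"-AVG" reference
# suffixes). Referential PSG labels like "F4-M1" are left intact.
normalizeChannelLabel <- function(lab) {
  lab <- trimws(lab)
  lab <- sub("^EEG[ _]+", "", lab, ignore.case = TRUE)
  lab <- sub("-(REF|LE|AVG)$", "", lab, ignore.case = TRUE)
  canon <- c(wakeMontage(), "A1", "A2", "M1", "M2",
             "F4-M1", "C4-M1", "O2-M1", "F3-M2", "C3-M2", "O1-M2",
             "FT7", "FT8", "FC3", "FC4", "FCz", "CP3", "CP4", "CPz",
             "TP7", "TP8", "POz", "AFz", "T3", "T4", "T5", "T6")
  hit <- match(toupper(lab), toupper(canon))
  ifelse(is.na(hit), lab, canon[hit])
}

#' Read a multichannel recording from disk
#'
#' Supported formats: \code{"edf"} (16-bit European Data Format; sampling
#' rate and physical units from the header, labels normalized to 10-20
#' names) and \code{"delimited"} (tab-separated numeric matrix, one column
#' per channel, channel-name header; a leading \code{# sfreq <Hz>} comment
#' carries the sampling rate, else pass \code{sfreq}). \code{"auto"}
#' decides by the EDF magic byte.
#'
#' @param path file path.
#' @param format "auto", "edf" or "delimited".
#' @param sfreq sampling rate in Hz, required for delimited files without
#'   a sfreq comment line.
#' @param meta metadata list attached to the Recording.
#' @return A \linkS4class{Recording} in microvolts.
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited"),
                          sfreq = NULL, meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    head8 <- readBin(path, "raw", 8)
    format <- if (identical(rawToChar(head8), "0       ")) "edf"
              else "delimited"
  }
  if (format == "edf") return(readEdf(path, meta = meta))
  lines1 <- readLines(path, n = 2)
  if (grepl("^#\\s*sfreq\\s", lines1[1])) {
    sfreq <- as.numeric(sub("^#\\s*sfreq\\s+", "", lines1[1]))
    skip <- 1L
  } else skip <- 0L
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           check.names = FALSE, comment.char = "")
  if (is.null(sfreq) || is.na(sfreq))
    stop("sampling rate unresolvable: no '# sfreq' line and no sfreq argument")
  labs <- normalizeChannelLabel(colnames(tab))
  if (anyDuplicated(labs))
    stop(sprintf("duplicate channel label(s): %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  m <- t(as.matrix(tab))
  if (!is.numeric(m) || anyNA(m))
    stop(sprintf("unparseable delimited recording: non-numeric or missing values in %s", path))
  Recording(m, labs, sfreq, meta)
}

#' Write a recording to disk
#'
#' @param rec a \linkS4class{Recording}.
#' @param path output path.
#' @param format "delimited" (default) or "edf".
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(is(rec, "Recording"))
  if (format == "edf") return(writeEdf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sfreq %g", rec@sfreq), con)
  utils::write.table(t(rec@data), con, sep = "\t", row.names = FALSE,
                     col.names = rec@channelNames, quote = FALSE)
  invisible(path)
}

#' Read / write a hypnogram
#'
#' Two-column tab-delimited text: epoch index and AASM stage label
#' (W, N1, N2, N3, R), one row per 30-s epoch.
#'
#' @param path file path.
#' @param epochLength epoch length in seconds (default 30).
#' @return \code{readHypnogram}: a \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path, epochLength = 30) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(tab)))
    stop("hypnogram file needs columns epoch_index and stage")
  tab <- tab[order(tab$epoch_index), ]
  Hypnogram(tab$stage, epochLength)
}

#' @rdname readHypnogram
#' @param h a \linkS4class{Hypnogram}.
#' @export
writeHypnogram <- function(h, path) {
  stopifnot(is(h, "Hypnogram"))
  utils::write.table(
    data.frame(epoch_index = seq_along(h@stages), stage = h@stages),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a simulation config as YAML
#'
#' @param path file path.
#' @return \code{readSimConfig}: a validated \code{\link{simConfig}}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$bands <- if (!is.null(y$bands))
    do.call(rbind.data.frame, y$bands) else eegBands()
  y$bandPowerBaseline <- unlist(y$bandPowerBaseline)
  if (!is.null(y$stageGains)) {
    sg <- do.call(rbind, lapply(y$stageGains, unlist))
  } else sg <- defaultStageGains()
  y$stageGains <- sg
  do.call(simConfig, y[setdiff(names(y), character())])
}

#' @rdname readSimConfig
#' @param cfg a \code{\link{simConfig}}.
#' @export
writeSimConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "SimConfig"))
  y <- unclass(cfg)
  y$bands <- lapply(seq_len(nrow(cfg$bands)), function(i)
    as.list(cfg$bands[i, ]))
  y$bandPowerBaseline <- as.list(cfg$bandPowerBaseline)
  y$stageGains <- lapply(seq_len(nrow(cfg$stageGains)), function(i)
    as.list(cfg$stageGains[i, ]))
  names(y$stageGains) <- rownames(cfg$stageGains)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth a ground-truth list from the generator.
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
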
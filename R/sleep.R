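#' Sleep architecture summary
#'
#' Standard architecture variables from a hypnogram: time in bed (TIB, the
#' lights-off to lights-on span), total sleep time (TST, minutes staged
#' N1/N2/N3/R), sleep efficiency (SE = TST/TIB), sleep latency (SL,
#' minutes from lights off to the first non-W epoch), wake after sleep
#' onset (WASO, W minutes between sleep onset and lights on — no
#' final-awakening trimming), and NREM/REM minutes.
#'
#' @param h a \linkS4class{Hypnogram}.
#' @return list with tib, tst, se, sl, waso, nremMinutes, remMinutes (all
#'   minutes except se). With no sleep epoch, sl and waso are NA and
#'   tst = se = 0.
#' @export
scoreArchitecture <- function(h) {
  stopifnot(is(h, "Hypnogram"))
  epm <- h@epochLength / 60  # minutes per epoch
  span <- h@lightsOff:h@lightsOn
  st <- h@stages[span]
  tib <- length(span) * epm
  sleepEp <- st %in% c("N1", "N2", "N3", "R")
  tst <- sum(sleepEp) * epm
  nrem <- sum(st %in% c("N1", "N2", "N3")) * epm
  rem <- sum(st == "R") * epm
  if (!any(sleepEp)) {
    return(list(tib = tib, tst = 0, se = 0, sl = NA_real_, waso = NA_real_,
                nremMinutes = 0, remMinutes = 0))
  }
  onset <- which(sleepEp)[1]
  sl <- (onset - 1) * epm
  waso <- sum(st[onset:length(st)] == "W") * epm
  list(tib = tib, tst = tst, se = tst / tib, sl = sl, waso = waso,
       nremMinutes = nrem, remMinutes = rem)
}

#' Detect NREM-REM sleep cycles (Feinberg-Floyd criteria)
#'
#' Scans the hypnogram for maximal NREM periods — runs of N1/N2/N3 in
#' which interruptions (W, or REM runs too short to qualify as REM
#' periods) shorter than \code{interruptTolerance} minutes do not split
#' the period — of at least \code{minNrem} minutes of NREM sleep, each
#' paired with the subsequent REM period of at least \code{minRem}
#' minutes. The first REM period of the night is exempt from the REM
#' minimum when \code{firstRemExempt} (short or fragmentary first REM is
#' common). A trailing qualifying NREM period without terminal REM forms a
#' final incomplete cycle only when \code{allowIncompleteFinal}.
#'
#' @param h a \linkS4class{Hypnogram}.
#' @param minNrem minimum NREM minutes per period (default 15).
#' @param minRem minimum REM minutes per period (default 5).
#' @param firstRemExempt exempt the night's first REM run from the REM
#'   minimum (default TRUE).
#' @param interruptTolerance interruptions strictly shorter than this many
#'   minutes do not split an NREM period (default 5).
#' @param allowIncompleteFinal keep a trailing REM-less NREM period as an
#'   incomplete final cycle (default FALSE).
#' @return A \linkS4class{SleepCycleSet}; empty (with a warning) if no
#'   qualifying NREM period exists.
#' @export
detectCycles <- function(h, minNrem = 15, minRem = 5,
                         firstRemExempt = TRUE, interruptTolerance = 5,
                         allowIncompleteFinal = FALSE) {
  stopifnot(is(h, "Hypnogram"))
  epm <- h@epochLength / 60
  cls <- ifelse(h@stages %in% c("N1", "N2", "N3"), "N",
                ifelse(h@stages == "R", "R", "W"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nRuns <- length(r$values)
  # which R runs qualify as REM periods
  rIdx <- which(r$values == "R")
  remQualifies <- logical(nRuns)
  for (j in rIdx) {
    dur <- r$lengths[j] * epm
    isFirst <- j == rIdx[1]
    remQualifies[j] <- dur >= minRem || (isFirst && firstRemExempt)
  }
  tolEpochs <- interruptTolerance / epm
  cycRows <- list()
  curStart <- NA_integer_; curEnd <- NA_integer_; curNremEpochs <- 0L
  pendingNrem <- NULL  # qualifying NREM period awaiting its REM period
  closeNrem <- function() {
    if (!is.na(curStart) && curNremEpochs * epm >= minNrem)
      list(start = curStart, end = curEnd)
    else NULL
  }
  i <- 1L
  while (i <= nRuns) {
    v <- r$values[i]
    if (v == "N") {
      if (is.na(curStart)) curStart <- starts[i]
      curEnd <- ends[i]
      curNremEpochs <- curNremEpochs + r$lengths[i]
    } else if (v == "R" && remQualifies[i]) {
      per <- closeNrem()
      curStart <- NA_integer_; curNremEpochs <- 0L
      # merge subsequent R runs separated by short W-only gaps
      remStart <- starts[i]; remEnd <- ends[i]
      j <- i + 1L
      while (j + 1L <= nRuns && r$values[j] == "W" &&
             r$lengths[j] < tolEpochs && r$values[j + 1L] == "R") {
        remEnd <- ends[j + 1L]
        j <- j + 2L
      }
      i <- j - 1L
      if (!is.null(per)) {
        cycRows[[length(cycRows) + 1L]] <-
          data.frame(nremStart = per$start, nremEnd = per$end,
                     remStart = remStart, remEnd = remEnd)
      }
    } else {
      # W run, or non-qualifying R run: splits only if >= tolerance
      if (r$lengths[i] >= tolEpochs) {
        per <- closeNrem()
        if (!is.null(per) && allowIncompleteFinal && i == nRuns) {
          cycRows[[length(cycRows) + 1L]] <-
            data.frame(nremStart = per$start, nremEnd = per$end,
                       remStart = NA_integer_, remEnd = NA_integer_)
        }
        curStart <- NA_integer_; curNremEpochs <- 0L
      }
    }
    i <- i + 1L
  }
  per <- closeNrem()
  if (!is.null(per) && allowIncompleteFinal) {
    cycRows[[length(cycRows) + 1L]] <-
      data.frame(nremStart = per$start, nremEnd = per$end,
                 remStart = NA_integer_, remEnd = NA_integer_)
  }
  cyc <- if (length(cycRows)) do.call(rbind, cycRows) else
    data.frame(nremStart = integer(), nremEnd = integer(),
               remStart = integer(), remEnd = integer())
  if (nrow(cyc) == 0L)
    warning("no qualifying NREM period: empty cycle set", call. = FALSE)
  new("SleepCycleSet", cycles = cyc,
      ruleParams = list(minNrem = minNrem, minRem = minRem,
                        firstRemExempt = firstRemExempt,
                        interruptTolerance = interruptTolerance,
                        allowIncompleteFinal = allowIncompleteFinal))
}

#' First-sleep-cycle NREM spectra and connectivity
#'
#' Extracts the N1/N2/N3-staged 30-s epochs within the NREM period of the
#' first detected cycle, applies the sleep artifact rules (threshold
#' marking on the preprocessed signal and the >50\% channel-exclusion
#' rule), and computes the Welch band-power table and, when at least
#' \code{minPlvChannels} channels remain, a PLV matrix per band.
#'
#' @param rec the night's \linkS4class{Recording} (PSG EEG channels),
#'   aligned to the hypnogram's epoch 1 at sample 1.
#' @param h the night's \linkS4class{Hypnogram}.
#' @param cyc a \linkS4class{SleepCycleSet} with >= 1 cycle.
#' @param bands band definitions (default \code{eegBands()}).
#' @param threshold artifact threshold in microvolts (default 100).
#' @param maxArtifactFraction channel-exclusion fraction (default 0.5).
#' @param preprocess run \code{\link{preprocessSleep}} first (default TRUE).
#' @param minPlvChannels minimum retained channels for PLV (default 6).
#' @return list with \code{bandPower} (a \linkS4class{BandPowerTable}),
#'   \code{plv} (named list of \linkS4class{PLVMatrix} or NULL),
#'   \code{nEpochs}, \code{montage}.
#' @export
firstCycleNremSpectra <- function(rec, h, cyc, bands = eegBands(),
                                  threshold = 100,
                                  maxArtifactFraction = 0.5,
                                  preprocess = TRUE,
                                  minPlvChannels = 6) {
  stopifnot(is(rec, "Recording"), is(h, "Hypnogram"),
            is(cyc, "SleepCycleSet"))
  if (nrow(cyc@cycles) < 1L)
    stop("no detected sleep cycle")
  span <- cyc@cycles$nremStart[1]:cyc@cycles$nremEnd[1]
  nremIdx <- span[h@stages[span] %in% c("N1", "N2", "N3")]
  spe <- round(h@epochLength * rec@sfreq)
  if (ncol(rec@data) < max(nremIdx) * spe)
    stop("recording does not cover the first cycle's NREM period")
  if (preprocess) rec <- preprocessSleep(rec)
  es <- segmentAndReject(rec, h@epochLength, threshold)
  es <- subsetEpochs(es, nremIdx)
  es <- excludeBadChannels(es, maxArtifactFraction)
  if (length(es@keptIndices) == 0L)
    stopNoData("all first-cycle NREM epochs are artifactual")
  meta <- c(rec@meta, list(context = "firstCycleNREM"))
  bp <- bandPower(welchPsd(es), bands = bands, meta = meta)
  plv <- NULL
  if (length(es@channelNames) >= minPlvChannels) {
    plv <- lapply(seq_len(nrow(bands)), function(b)
      phaseLockingValue(es, bands[b, ], meta = meta))
    names(plv) <- bands$name
  }
  list(bandPower = bp, plv = plv, nEpochs = length(es@keptIndices),
       montage = es@channelNames)
}
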
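#' Validate a study manifest
#'
#' A manifest drives the pipeline from recordings on disk: one row per
#' (subject, arm, timepoint) with the file path, plus optional sleep rows
#' (\code{timepoint == "night"}) carrying a \code{hypnogram} path.
#'
#' @param manifest data.frame with columns subject, arm, timepoint, path
#'   (and optionally hypnogram).
#' @return the manifest, invisibly, after validation.
#' @export
validateManifest <- function(manifest) {
  need <- c("subject", "arm", "timepoint", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns subject, arm, timepoint, path")
  key <- interaction(manifest$subject, manifest$arm, manifest$timepoint)
  if (anyDuplicated(key))
    stop("manifest rows must be unique in (subject, arm, timepoint)")
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing))
    stop(sprintf("manifest file(s) not found: %s",
                 paste(missing, collapse = ", ")))
  invisible(manifest)
}

wakeStageTables <- function(recs, bands, epochLength, threshold) {
  lapply(recs, function(rec) {
    pre <- preprocessWake(rec)
    es <- segmentAndReject(pre, epochLength, threshold)
    bandPower(welchPsd(es), bands = bands, meta = rec@meta)
  })
}

#' Run the full study analysis
#'
#' Orchestrates the end-to-end analysis of a crossover EEG study:
#' simulate (or read) the wake recordings for every subject, arm and
#' timepoint; preprocess, segment and screen them; estimate per-channel
#' band power and, for the requested bands, PLV networks and their graph
#' metrics; run the paired contrasts with BH-FDR across electrodes, the
#' two-way repeated-measures ANOVA on each network metric, and the
#' post-minus-baseline z-scores at the target electrode; optionally
#' simulate and analyze one sleep night per subject and arm, detect
#' Feinberg-Floyd cycles, and correlate the wake band-power change with
#' first-cycle NREM power. All stages derive their randomness from
#' \code{cfg$seed}, so a rerun with the same config is identical.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir output directory for tables and the JSON summary; NULL
#'   skips writing.
#' @param timepoints timepoints to analyze (default T1..T6).
#' @param plvBands band names for connectivity/network analysis (default
#'   delta and theta).
#' @param alpha FDR-corrected significance level (default 0.05).
#' @param displayAlpha stricter display threshold used to flag edges in
#'   the network summary (default 0.005).
#' @param targetChannel electrode for the band-power-change analysis
#'   (default "F4", the stimulation target).
#' @param sleepTargetChannel matching sleep-montage electrode (default
#'   "F4-M1").
#' @param sleep analyze sleep nights (default TRUE).
#' @param manifest optional manifest (see \code{\link{validateManifest}});
#'   when given, wake recordings are read from its paths instead of
#'   simulated.
#' @param epochLength wake epoch length in seconds (default 5).
#' @param threshold artifact threshold in microvolts (default 100).
#' @param keepPlvEdges also return the long-form PLV edge table per
#'   subject, arm, timepoint and band (default FALSE).
#' @return list with tables \code{bandPower}, \code{psdTests},
#'   \code{networkMetrics}, \code{networkAnova}, \code{deltaPsd},
#'   \code{sleepArchitecture}, \code{wakeSleepCorrelation}, and
#'   \code{summary}.
#' @export
runPipeline <- function(cfg, outdir = NULL,
                        timepoints = paste0("T", 1:6),
                        plvBands = c("delta", "theta"),
                        alpha = 0.05, displayAlpha = 0.005,
                        targetChannel = "F4",
                        sleepTargetChannel = "F4-M1",
                        sleep = TRUE, manifest = NULL,
                        epochLength = 5, threshold = 100,
                        keepPlvEdges = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"))
  arms <- c("active", "sham")
  subjects <- seq_len(cfg$nSubjects)
  bands <- cfg$bands
  if (!is.null(manifest)) validateManifest(manifest)

  getRecording <- function(s, arm, tp) {
    if (is.null(manifest))
      return(simulateWakeRecording(cfg, s, arm, tp)$recording)
    row <- manifest[manifest$subject == s & manifest$arm == arm &
                      manifest$timepoint == tp, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    readRecording(row$path[1], sfreq = cfg$sfreqWake,
                  meta = list(subject = s, arm = arm, timepoint = tp))
  }

  bp <- list()       # bandPower tables keyed subject|arm|tp
  netRows <- list()
  edgeRows <- list()
  for (arm in arms) for (s in subjects) for (tp in timepoints) {
    rec <- getRecording(s, arm, tp)
    if (is.null(rec)) next
    if (all(wakeMontage() %in% rec@channelNames))
      rec <- selectChannels(rec, wakeMontage())
    pre <- preprocessWake(rec)
    es <- segmentAndReject(pre, epochLength, threshold)
    key <- paste(s, arm, tp, sep = "|")
    bp[[key]] <- bandPower(welchPsd(es), bands = bands, meta = rec@meta)
    for (bn in plvBands) {
      plv <- phaseLockingValue(es, bands[bands$name == bn, ],
                               meta = rec@meta)
      nm <- networkMetrics(plv)
      netRows[[paste(key, bn)]] <- data.frame(
        subject = s, arm = arm, timepoint = tp, band = bn,
        cc = nm$cc, cpl = nm$cpl, ge = nm$ge, le = nm$le,
        stringsAsFactors = FALSE)
      if (keepPlvEdges)
        edgeRows[[paste(key, bn)]] <- cbind(
          subject = s, arm = arm, timepoint = tp, plvEdgeTable(plv))
    }
  }
  netTab <- if (length(netRows)) do.call(rbind, netRows) else NULL
  if (!is.null(netTab)) rownames(netTab) <- NULL

  bpLong <- do.call(rbind, lapply(bp, bandPowerTable))
  rownames(bpLong) <- NULL

  # paired contrasts: baseline vs each later timepoint, per band and arm,
  # BH-FDR within each (band x comparison x arm) electrode family
  base <- timepoints[1]
  psdTests <- list()
  for (arm in arms) for (bn in bands$name) for (tp in setdiff(timepoints, base)) {
    mats <- lapply(c(base, tp), function(t0) {
      keys <- paste(subjects, arm, t0, sep = "|")
      if (!all(keys %in% names(bp))) return(NULL)
      do.call(rbind, lapply(keys, function(k) bandValues(bp[[k]])[, bn]))
    })
    if (any(vapply(mats, is.null, TRUE))) next
    res <- pairedTFdr(mats[[1]], mats[[2]], alpha = alpha,
                      comparison = paste(base, "vs", tp))
    res$band <- bn; res$arm <- arm
    psdTests[[paste(arm, bn, tp)]] <- res
  }
  psdTests <- if (length(psdTests)) do.call(rbind, psdTests) else NULL
  if (!is.null(psdTests)) rownames(psdTests) <- NULL

  # repeated-measures ANOVA on each network metric, per band
  netAnova <- NULL
  if (!is.null(netTab) && length(unique(netTab$arm)) == 2 &&
      length(timepoints) >= 2) {
    rows <- list()
    complete <- all(table(netTab$subject, netTab$arm, netTab$timepoint,
                          netTab$band) == 1)
    if (complete) {
      for (bn in unique(netTab$band)) for (m in c("cc", "cpl", "ge", "le")) {
        d <- netTab[netTab$band == bn, ]
        an <- rmAnova(data.frame(subject = d$subject, arm = d$arm,
                                 time = d$timepoint, value = d[[m]]))
        an$band <- bn; an$metric <- m
        rows[[paste(bn, m)]] <- an
      }
      netAnova <- do.call(rbind, rows)
      rownames(netAnova) <- NULL
    }
  }

  # post-minus-baseline change at the target electrode, z-scored
  deltaPsd <- list()
  last <- timepoints[length(timepoints)]
  for (arm in arms) {
    keysA <- paste(subjects, arm, base, sep = "|")
    keysB <- paste(subjects, arm, last, sep = "|")
    haveA <- keysA %in% names(bp); haveB <- keysB %in% names(bp)
    if (!any(haveA) && !any(haveB)) next
    baseline <- stats::setNames(bp[keysA[haveA]],
                                as.character(subjects[haveA]))
    post <- stats::setNames(bp[keysB[haveB]],
                            as.character(subjects[haveB]))
    dz <- deltaPsdZscores(baseline, post, targetChannel)
    dz$arm <- arm
    deltaPsd[[arm]] <- dz
  }
  deltaPsd <- if (length(deltaPsd)) do.call(rbind, deltaPsd) else NULL
  if (!is.null(deltaPsd)) rownames(deltaPsd) <- NULL

  # sleep: one night per subject and arm
  archRows <- list(); sleepPower <- list(); corRows <- list()
  if (sleep && is.null(manifest)) {
    for (arm in arms) for (s in subjects) {
      night <- simulateSleepNight(cfg, s, arm)
      cyc <- detectCycles(night$hypnogram)
      arch <- scoreArchitecture(night$hypnogram)
      archRows[[paste(s, arm)]] <- data.frame(
        subject = s, arm = arm, as.data.frame(arch),
        nCycles = nrow(cycles(cyc)), stringsAsFactors = FALSE)
      if (nrow(cycles(cyc)) >= 1) {
        fc <- firstCycleNremSpectra(night$recording, night$hypnogram, cyc,
                                    bands = bands, threshold = threshold)
        sleepPower[[paste(s, arm)]] <- cbind(
          subject = s, arm = arm, bandPowerTable(fc$bandPower))
      }
    }
    spTab <- if (length(sleepPower)) do.call(rbind, sleepPower) else NULL
    if (!is.null(spTab) && !is.null(deltaPsd)) {
      for (arm in arms) for (bn in bands$name) {
        dz <- deltaPsd[deltaPsd$arm == arm & deltaPsd$band == bn, ]
        sp <- spTab[spTab$arm == arm & spTab$band == bn &
                      spTab$channel == sleepTargetChannel, ]
        common <- intersect(dz$subject, sp$subject)
        if (length(common) < 3) next
        ct <- wakeSleepCorrelation(
          dz$zscore[match(common, dz$subject)],
          sp$value[match(common, sp$subject)])
        corRows[[paste(arm, bn)]] <- data.frame(
          arm = arm, band = bn, r = ct$r, p = ct$p, n = ct$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  archTab <- if (length(archRows)) do.call(rbind, archRows) else NULL
  corTab <- if (length(corRows)) do.call(rbind, corRows) else NULL
  if (!is.null(archTab)) rownames(archTab) <- NULL
  if (!is.null(corTab)) rownames(corTab) <- NULL

  summaryList <- list(
    seed = cfg$seed,
    nSubjects = cfg$nSubjects,
    timepoints = timepoints,
    nSignificantElectrodes = if (!is.null(psdTests))
      stats::aggregate(significant ~ arm + band + comparison,
                       data = psdTests, FUN = sum) else NULL,
    displayAlpha = displayAlpha,
    alpha = alpha
  )
  out <- list(bandPower = bpLong, psdTests = psdTests,
              networkMetrics = netTab, networkAnova = netAnova,
              deltaPsd = deltaPsd, sleepArchitecture = archTab,
              wakeSleepCorrelation = corTab, summary = summaryList)
  if (keepPlvEdges && length(edgeRows)) {
    out$plvEdges <- do.call(rbind, edgeRows)
    rownames(out$plvEdges) <- NULL
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("bandPower", "psdTests", "networkMetrics", "networkAnova",
                 "deltaPsd", "sleepArchitecture", "wakeSleepCorrelation")) {
      if (!is.null(out[[nm]]))
        utils::write.table(out[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summaryList, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
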
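# Synthetic crossover-study generator: wake recordings at six timepoints
# under active/sham arms with controllable band power, inter-channel phase
# coupling, amplitude artifacts and line noise, plus sleep PSG nights with
# a generated hypnogram and stage-dependent spectra. Every downstream
# stage is validated against the ground truth this module records.

.calibCache <- new.env(parent = emptyenv())

# Expected fraction of a flat in-band PSD that a Hamming-windowed
# periodogram of segment length nSeg retains, on average over the band's
# in-band bins: the window's spectral kernel smears edge-bin energy out
# of the band, so the mean measured in-band PSD of brick-wall band noise
# is slightly below its true density (~9% for a 3 Hz band at 5 s
# segments). Computed from the window's squared transfer kernel on an
# oversampled grid; cached per (nSeg, sfreq, band).
windowRetention <- function(nSeg, sfreq, flo, fhi, os = 16) {
  key <- sprintf("ret_%d_%g_%g_%g", nSeg, sfreq, flo, fhi)
  if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
  w <- hammingWindow(nSeg)
  U <- sum(w^2)
  Nf <- nSeg * os
  K <- Mod(stats::fft(c(w, numeric(Nf - nSeg))))^2 / (sfreq * U)
  df <- sfreq / Nf
  fCoarse <- (0:(nSeg - 1)) * sfreq / nSeg
  kBins <- which(fCoarse >= flo & fCoarse < fhi) - 1L
  fFine <- (0:(Nf - 1)) * df
  mBand <- which(fFine >= flo & fFine < fhi) - 1L
  ret <- mean(vapply(kBins, function(k) {
    sum(K[((mBand - k * os) %% Nf) + 1L]) * df
  }, numeric(1)))
  .calibCache[[key]] <- ret
  ret
}

# Band-limited Gaussian noise calibrated so that the mean Welch PSD over
# the band's bins equals targetPsd (microV^2/Hz) in expectation, at the
# analysis segmentation the study prescribes: white noise band-limited in
# the spectral domain with the same half-open band edges
# (flo <= f < fhi) the spectral module uses, then scaled up by the
# window-retention factor of the analyzing periodogram.
bandNoise <- function(n, sfreq, flo, fhi, targetPsd,
                      analysisEpochLength = 5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * sfreq / n
  f <- pmin(f, sfreq - f)          # fold the negative-frequency half
  keep <- f >= flo & f < fhi
  X[!keep] <- 0
  # exact-power synthesis: rescale the realization so its in-band power
  # equals the expectation, removing the chi-square amplitude fluctuation
  # of the draw (the spectral shape stays random)
  m <- sum(keep)
  X <- X * sqrt(as.double(n) * m / sum(Mod(X[keep])^2))
  ret <- windowRetention(round(analysisEpochLength * sfreq), sfreq,
                         flo, fhi)
  Re(stats::fft(X, inverse = TRUE) / n) * sqrt(targetPsd * sfreq / (2 * ret))
}

#' Simulation configuration for a synthetic crossover EEG study
#'
#' Defines the study conditions the generator reproduces: a six-timepoint
#' active/sham crossover of eyes-closed wake recordings plus one sleep
#' night per subject and arm. Band-limited noise per channel realizes the
#' configured band powers; the active arm multiplies delta and theta power
#' by a non-decreasing per-timepoint gain ramp; configured channel pairs
#' share a narrowband source at a given coupling strength; sporadic
#' +/-150 microvolt transients and 50 Hz line noise are injected.
#'
#' @param nSubjects number of subjects (default 20).
#' @param sfreqWake wake sampling rate, Hz (default 1000).
#' @param sfreqSleep sleep PSG sampling rate, Hz (default 512).
#' @param wakeDuration seconds of wake EEG per timepoint (default 300).
#' @param channelSet wake channel labels (default the 21-channel 10-20
#'   montage of \code{\link{wakeMontage}}).
#' @param bandPowerBaseline named vector, band -> mean in-band PSD in
#'   microV^2/Hz.
#' @param activeEffectRamp length-6 non-decreasing multiplicative gain on
#'   delta/theta power in the active arm, first element 1 (baseline T1
#'   unmodified); default reaches +30\% at T6.
#' @param couplingPairs list of lists with elements \code{a}, \code{b}
#'   (channel labels), \code{band}, \code{strength} in [0, 1].
#' @param artifactRate artifact events per minute (default 2).
#' @param lineNoiseAmplitude 50 Hz sinusoid amplitude in microvolts
#'   (default 5).
#' @param seed integer base seed; all per-(subject, arm, timepoint)
#'   substreams derive from it deterministically.
#' @param bands band definitions (default \code{\link{eegBands}}).
#' @param sleepChannelSet sleep montage labels (default the 6-channel
#'   referential PSG montage).
#' @param sleepTibMinutes target time in bed for generated nights, minutes
#'   (default 480).
#' @param stageGains band x stage multiplicative gains on
#'   \code{bandPowerBaseline} during sleep; the default gives delta power
#'   the ordering N3 > N2 > N1 > R = W, with N3 delta 10x wake delta.
#' @param subjectVariability SD of a lognormal per-subject modulation of
#'   the active-arm theta effect, shared between wake and sleep (0 = off).
#'   When positive, subjects with a larger wake theta gain also get
#'   proportionally more sleep theta power, coupling the two measurements.
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nSubjects = 2, wakeDuration = 20)
#' @export
simConfig <- function(nSubjects = 20,
                      sfreqWake = 1000,
                      sfreqSleep = 512,
                      wakeDuration = 300,
                      channelSet = wakeMontage(),
                      bandPowerBaseline = c(delta = 2, theta = 1.5,
                                            alpha = 2, beta = 0.5,
                                            gamma = 0.1),
                      activeEffectRamp = c(1, 1.10, 1.15, 1.20, 1.25, 1.30),
                      couplingPairs = list(
                        list(a = "F4", b = "O1", band = "theta",
                             strength = 0.8)),
                      artifactRate = 2,
                      lineNoiseAmplitude = 5,
                      seed = 1L,
                      bands = eegBands(),
                      sleepChannelSet = c("F4-M1", "C4-M1", "O2-M1",
                                          "F3-M2", "C3-M2", "O1-M2"),
                      sleepTibMinutes = 480,
                      stageGains = defaultStageGains(),
                      subjectVariability = 0) {
  cfg <- list(nSubjects = as.integer(nSubjects), sfreqWake = sfreqWake,
              sfreqSleep = sfreqSleep, wakeDuration = wakeDuration,
              channelSet = channelSet,
              bandPowerBaseline = bandPowerBaseline,
              activeEffectRamp = activeEffectRamp,
              couplingPairs = couplingPairs,
              artifactRate = artifactRate,
              lineNoiseAmplitude = lineNoiseAmplitude,
              seed = as.integer(seed), bands = bands,
              sleepChannelSet = sleepChannelSet,
              sleepTibMinutes = sleepTibMinutes,
              stageGains = stageGains,
              subjectVariability = subjectVariability)
  validateSimConfig(cfg)
  structure(cfg, class = "SimConfig")
}

#' @rdname simConfig
#' @return \code{defaultStageGains}: the default band x stage gain matrix.
#' @export
defaultStageGains <- function() {
  g <- rbind(
    delta = c(W = 1, N1 = 1.5, N2 = 4,   N3 = 10,  R = 1),
    theta = c(W = 1, N1 = 1.5, N2 = 2,   N3 = 2.5, R = 1.2),
    alpha = c(W = 1, N1 = 0.6, N2 = 0.4, N3 = 0.3, R = 0.5),
    beta  = c(W = 1, N1 = 0.7, N2 = 0.5, N3 = 0.3, R = 0.8),
    gamma = c(W = 1, N1 = 0.7, N2 = 0.5, N3 = 0.4, R = 0.8)
  )
  g
}

validateSimConfig <- function(cfg) {
  if (length(cfg$activeEffectRamp) != 6)
    stop("activeEffectRamp must have length 6 (timepoints T1..T6)")
  if (cfg$activeEffectRamp[1] != 1)
    stop("activeEffectRamp[1] must be 1 (baseline T1 unmodified)")
  if (is.unsorted(cfg$activeEffectRamp))
    stop("activeEffectRamp must be non-decreasing")
  if (any(cfg$bandPowerBaseline <= 0))
    stop("all baseline band powers must be positive")
  for (cp in cfg$couplingPairs) {
    if (cp$strength < 0 || cp$strength > 1)
      stop("coupling strengths must lie in [0, 1]")
    if (!cp$band %in% cfg$bands$name)
      stop(sprintf("coupling pair names unknown band '%s'", cp$band))
  }
  hi <- max(cfg$bands$fhi)
  if (cfg$sfreqWake <= 2 * hi || cfg$sfreqSleep <= 2 * hi)
    stop(sprintf("sampling rates must exceed twice the highest band edge (%g Hz)", hi))
  if (anyDuplicated(cfg$channelSet))
    stop("channelSet labels must be unique")
  if (cfg$artifactRate < 0 || cfg$lineNoiseAmplitude < 0)
    stop("artifactRate and lineNoiseAmplitude must be non-negative")
  invisible(TRUE)
}

armIndex <- function(arm) {
  i <- match(arm, c("sham", "active"))
  if (is.na(i))
    stop(sprintf("invalid arm '%s': must be 'active' or 'sham'", arm))
  i
}

timepointIndex <- function(timepoint) {
  if (is.numeric(timepoint)) tp <- as.integer(timepoint)
  else tp <- match(toupper(timepoint), paste0("T", 1:6))
  if (is.na(tp) || tp < 1L || tp > 6L)
    stop(sprintf("invalid timepoint '%s': must be T1..T6", timepoint))
  tp
}

# Per-subject lognormal modulation of the active-arm theta effect,
# deterministic in (seed, subject) and shared between wake and sleep.
subjectThetaFactor <- function(cfg, subject) {
  if (cfg$subjectVariability <= 0) return(1)
  set.seed(substreamSeed(cfg$seed, subject, 777))
  exp(stats::rnorm(1, 0, cfg$subjectVariability))
}

# Band gains for one subject/arm/timepoint: the active arm scales delta
# and theta by the ramp; the theta effect is additionally modulated by the
# subject factor.
wakeBandGains <- function(cfg, subject, arm, tp) {
  g <- rep(1, nrow(cfg$bands)); names(g) <- cfg$bands$name
  if (arm == "active") {
    ramp <- cfg$activeEffectRamp[tp]
    g["delta"] <- ramp
    g["theta"] <- 1 + (ramp - 1) * subjectThetaFactor(cfg, subject)
  }
  g
}

# Raised-cosine transient, 200 ms, peak +/-150 microvolts: unambiguously
# crosses the +/-100 microvolt artifact rule.
artifactPulse <- function(sfreq, amplitude = 150) {
  len <- round(0.2 * sfreq)
  amplitude * 0.5 * (1 - cos(2 * pi * (0:(len - 1)) / (len - 1)))
}

# Inject line noise and artifact transients in place; returns the modified
# data plus artifact bookkeeping (sample spans and affected epoch indices
# for the given epoch length).
injectNuisance <- function(data, sfreq, cfg, epochLength) {
  n <- ncol(data); nch <- nrow(data)
  if (cfg$lineNoiseAmplitude > 0) {
    tt <- (0:(n - 1)) / sfreq
    for (ch in seq_len(nch)) {
      phi <- stats::runif(1, 0, 2 * pi)
      data[ch, ] <- data[ch, ] +
        cfg$lineNoiseAmplitude * sin(2 * pi * 50 * tt + phi)
    }
  }
  spe <- round(epochLength * sfreq)
  nseg <- floor(n / spe)
  artifacts <- data.frame(channel = character(), start = integer(),
                          end = integer(), epoch = integer(),
                          stringsAsFactors = FALSE)
  if (cfg$artifactRate > 0 && nseg >= 1) {
    pulse <- artifactPulse(sfreq)
    len <- length(pulse)
    nArt <- stats::rpois(1, cfg$artifactRate * n / sfreq / 60)
    for (k in seq_len(nArt)) {
      ch <- sample.int(nch, 1)
      # place the pulse fully inside one analysis epoch, so the flagged
      # epoch is exactly the one whose amplitude crosses the threshold
      ep <- sample.int(nseg, 1)
      offset <- sample.int(spe - len + 1L, 1)
      start <- (ep - 1L) * spe + offset
      sgn <- sample(c(-1, 1), 1)
      data[ch, start:(start + len - 1L)] <-
        data[ch, start:(start + len - 1L)] + sgn * pulse
      artifacts <- rbind(artifacts, data.frame(
        channel = rownames(data)[ch], start = start,
        end = start + len - 1L, epoch = ep, stringsAsFactors = FALSE))
    }
  }
  epochIdx <- sort(unique(artifacts$epoch))
  list(data = data, artifacts = artifacts, artifactEpochs = epochIdx)
}

#' Simulate one wake resting-state recording
#'
#' Generates the eyes-closed wake EEG of one subject, intervention arm and
#' timepoint under the study design in \code{cfg}. Each band is realized
#' as band-limited filtered noise at the configured power (scaled by the
#' arm/timepoint gain on delta/theta in the active arm); configured
#' coupled pairs share a common narrowband source mixed to the stated
#' strength; artifacts are 200 ms raised-cosine transients exceeding
#' 100 microvolts; a 50 Hz sinusoid is added per channel. Deterministic
#' under (seed, subject, arm, timepoint).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param subject subject index (1..nSubjects).
#' @param arm "active" or "sham".
#' @param timepoint "T1".."T6" (or 1..6).
#' @return list with \code{recording} (a \linkS4class{Recording}) and
#'   \code{truth} (target band-power map per channel, gains, coupled
#'   pairs, artifact sample spans and 5-s epoch indices).
#' @export
simulateWakeRecording <- function(cfg, subject, arm, timepoint) {
  stopifnot(inherits(cfg, "SimConfig"))
  ai <- armIndex(arm)
  tp <- timepointIndex(timepoint)
  set.seed(substreamSeed(cfg$seed, subject, ai, tp))
  n <- round(cfg$wakeDuration * cfg$sfreqWake)
  chs <- cfg$channelSet
  nch <- length(chs)
  gains <- wakeBandGains(cfg, subject, arm, tp)
  target <- outer(rep(1, nch), cfg$bandPowerBaseline[cfg$bands$name]) *
    matrix(gains[cfg$bands$name], nch, nrow(cfg$bands), byrow = TRUE)
  dimnames(target) <- list(chs, cfg$bands$name)
  data <- matrix(0, nch, n, dimnames = list(chs, NULL))
  for (b in seq_len(nrow(cfg$bands))) {
    bn <- cfg$bands$name[b]
    flo <- cfg$bands$flo[b]; fhi <- cfg$bands$fhi[b]
    pairs <- Filter(function(cp) cp$band == bn &&
                      all(c(cp$a, cp$b) %in% chs), cfg$couplingPairs)
    coupled <- unlist(lapply(pairs, function(cp) c(cp$a, cp$b)))
    for (ch in seq_len(nch)) {
      if (chs[ch] %in% coupled) next
      data[ch, ] <- data[ch, ] + bandNoise(n, cfg$sfreqWake, flo, fhi,
                                           target[ch, b])
    }
    for (cp in pairs) {
      s <- cp$strength
      shared <- bandNoise(n, cfg$sfreqWake, flo, fhi, 1)
      for (lab in c(cp$a, cp$b)) {
        own <- bandNoise(n, cfg$sfreqWake, flo, fhi, 1)
        amp <- sqrt(target[lab, b])
        data[lab, ] <- data[lab, ] +
          amp * (sqrt(s) * shared + sqrt(1 - s) * own)
      }
    }
  }
  inj <- injectNuisance(data, cfg$sfreqWake, cfg, epochLength = 5)
  rec <- Recording(inj$data, chs, cfg$sfreqWake,
                   meta = list(subject = subject, arm = arm,
                               timepoint = paste0("T", tp)))
  list(recording = rec,
       truth = list(bandPower = target, gains = gains,
                    coupledPairs = Filter(function(cp)
                      all(c(cp$a, cp$b) %in% chs), cfg$couplingPairs),
                    artifacts = inj$artifacts,
                    artifactEpochs = inj$artifactEpochs,
                    thetaSubjectFactor = subjectThetaFactor(cfg, subject)))
}

# Structured hypnogram generator: wake onset, then repeated
# N1-N2-N3-N2-R cycles with stage durations drawn from plausible ranges
# (deep N3 concentrated in early cycles, REM lengthening across the
# night), until the target time in bed is reached.
generateHypnogram <- function(cfg) {
  tgt <- round(cfg$sleepTibMinutes * 2)  # epochs of 30 s
  st <- rep("W", sample(10:20, 1))
  cycle <- 1L
  firstRemEnd <- NA_integer_
  while (length(st) < tgt || is.na(firstRemEnd)) {
    st <- c(st,
      rep("N1", sample(2:4, 1)),
      rep("N2", sample(20:40, 1)),
      rep("N3", if (cycle <= 2) sample(20:40, 1) else sample(0:10, 1)),
      rep("N2", sample(4:16, 1)))
    if (stats::runif(1) < 0.3) st <- c(st, rep("W", sample(1:2, 1)))
    st <- c(st,
      rep("R", if (cycle == 1) sample(2:8, 1) else sample(20:40, 1)))
    if (is.na(firstRemEnd)) firstRemEnd <- length(st)
    cycle <- cycle + 1L
  }
  # never truncate inside the first NREM-REM cycle: the generated night
  # always contains at least one qualifying cycle
  cut <- max(tgt - 4L, firstRemEnd)
  st <- c(st[seq_len(min(length(st), cut))], rep("W", 4L))
  Hypnogram(st)
}

#' Simulate one sleep PSG night
#'
#' Generates a hypnogram by a structured stage-transition scheme (starting
#' in W, with a first NREM period well above 15 min followed by a REM
#' run), then synthesizes the PSG EEG per stage run with stage-dependent
#' band powers (default delta ordering N3 > N2 > N1 > R, W), plus the
#' configured artifacts and line noise. In the active arm the theta stage
#' power is scaled by the same subject-specific factor that modulates the
#' wake theta effect, so wake and sleep theta changes are coupled when
#' \code{subjectVariability > 0}. Deterministic under (seed, subject,
#' arm).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param subject subject index.
#' @param arm "active" or "sham".
#' @param stages optional forced stage sequence; when supplied the
#'   hypnogram is exactly this sequence.
#' @param eeg synthesize the PSG EEG (default TRUE); FALSE returns the
#'   hypnogram and ground truth only, with \code{recording = NULL} (fast
#'   path for architecture-level analyses).
#' @return list with \code{recording}, \code{hypnogram} and \code{truth}
#'   (stage-wise band-power map, stage counts, artifact 30-s epoch
#'   indices).
#' @export
simulateSleepNight <- function(cfg, subject, arm, stages = NULL,
                               eeg = TRUE) {
  stopifnot(inherits(cfg, "SimConfig"))
  ai <- armIndex(arm)
  set.seed(substreamSeed(cfg$seed, subject, ai, 500))
  h <- if (is.null(stages)) generateHypnogram(cfg) else Hypnogram(stages)
  chs <- cfg$sleepChannelSet
  nch <- length(chs)
  spe <- round(30 * cfg$sfreqSleep)
  n <- length(h@stages) * spe
  # active-arm theta modulation carried into sleep (end-of-ramp effect)
  thetaGain <- if (arm == "active")
    1 + (cfg$activeEffectRamp[6] - 1) * subjectThetaFactor(cfg, subject)
  else 1
  stageNames <- c("W", "N1", "N2", "N3", "R")
  stagePower <- sapply(stageNames, function(stg) {
    p <- cfg$bandPowerBaseline[cfg$bands$name] *
      cfg$stageGains[cfg$bands$name, stg]
    p["theta"] <- p["theta"] * thetaGain
    p
  })
  rownames(stagePower) <- cfg$bands$name
  if (!eeg) {
    return(list(recording = NULL, hypnogram = h,
                truth = list(stagePower = stagePower,
                             stageCounts = table(factor(h@stages,
                                                        stageNames)),
                             artifacts = NULL, artifactEpochs = integer(),
                             thetaGain = thetaGain)))
  }
  data <- matrix(0, nch, n, dimnames = list(chs, NULL))
  r <- rle(h@stages)
  pos <- 0L
  for (k in seq_along(r$values)) {
    len <- r$lengths[k] * spe
    idx <- (pos + 1L):(pos + len)
    stg <- r$values[k]
    for (b in seq_len(nrow(cfg$bands))) {
      flo <- cfg$bands$flo[b]; fhi <- cfg$bands$fhi[b]
      p <- stagePower[cfg$bands$name[b], stg]
      for (ch in seq_len(nch))
        data[ch, idx] <- data[ch, idx] +
          bandNoise(len, cfg$sfreqSleep, flo, fhi, p,
                    analysisEpochLength = 30)
    }
    pos <- pos + len
  }
  inj <- injectNuisance(data, cfg$sfreqSleep, cfg, epochLength = 30)
  rec <- Recording(inj$data, chs, cfg$sfreqSleep,
                   meta = list(subject = subject, arm = arm,
                               night = "experimental"))
  list(recording = rec, hypnogram = h,
       truth = list(stagePower = stagePower,
                    stageCounts = table(factor(h@stages, stageNames)),
                    artifacts = inj$artifacts,
                    artifactEpochs = inj$artifactEpochs,
                    thetaGain = thetaGain))
}
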
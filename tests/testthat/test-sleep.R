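# Hypnogram architecture, Feinberg-Floyd cycle detection, first-cycle
# NREM spectra.

test_that("architecture arithmetic on a forced stage sequence", {
  h <- Hypnogram(c(rep("W", 10), rep("N2", 40), rep("R", 12),
                   rep("W", 2)))
  a <- scoreArchitecture(h)
  expect_equal(a$tib, 32)
  expect_equal(a$tst, 26)
  expect_equal(a$sl, 5)
  expect_equal(a$nremMinutes, 20)
  expect_equal(a$remMinutes, 6)
  expect_equal(a$se, 26 / 32)
  expect_equal(a$waso, 1)
})

test_that("an all-wake night has no sleep and undefined latency", {
  a <- scoreArchitecture(Hypnogram(rep("W", 20)))
  expect_equal(a$tst, 0)
  expect_equal(a$se, 0)
  expect_true(is.na(a$sl))
})

test_that("minimal qualifying durations give exactly one full-record cycle", {
  h <- Hypnogram(c(rep("N2", 30), rep("R", 10)))
  cyc <- cycles(detectCycles(h))
  expect_equal(nrow(cyc), 1)
  expect_equal(unlist(cyc[1, ]), c(nremStart = 1, nremEnd = 30,
                                   remStart = 31, remEnd = 40))
})

test_that("an NREM period below 15 minutes yields no cycle", {
  h <- Hypnogram(c(rep("N2", 28), rep("R", 10)))
  expect_warning(cs <- detectCycles(h), "no qualifying")
  expect_equal(nrow(cycles(cs)), 0)
})

test_that("the first REM period is exempt from the 5-minute minimum", {
  h <- Hypnogram(c(rep("N2", 40), rep("R", 2), rep("N2", 40),
                   rep("R", 12)))
  cyc <- cycles(detectCycles(h))
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$remStart[1], 41)
  expect_equal(cyc$remEnd[1], 42)
  expect_equal(cyc$nremStart[2], 43)
  expect_equal(cyc$remEnd[2], 94)
  # with the exemption off, the 1-minute REM cannot close a cycle and the
  # two NREM blocks merge across it (interruption < tolerance)
  cyc2 <- cycles(detectCycles(h, firstRemExempt = FALSE))
  expect_equal(nrow(cyc2), 1)
  expect_equal(cyc2$nremStart[1], 1)
  expect_equal(cyc2$nremEnd[1], 82)
})

test_that("short wake interruptions do not split an NREM period", {
  h <- Hypnogram(c(rep("N2", 20), rep("W", 4), rep("N2", 20),
                   rep("R", 10)))
  cyc <- cycles(detectCycles(h))
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$nremEnd[1], 44)
  # a 5-minute wake run splits; neither half reaches 15 NREM minutes
  h2 <- Hypnogram(c(rep("N2", 20), rep("W", 10), rep("N2", 20),
                    rep("R", 10)))
  expect_warning(cs2 <- detectCycles(h2), "no qualifying")
  expect_equal(nrow(cycles(cs2)), 0)
})

test_that("trailing wake does not change the cycle decomposition", {
  h <- Hypnogram(c(rep("N2", 30), rep("R", 10)))
  h2 <- Hypnogram(c(stages(h), rep("W", 30)))
  expect_equal(cycles(detectCycles(h)), cycles(detectCycles(h2)))
})

test_that("cycles tile without overlap and stay within TST on generated nights", {
  cfg <- simConfig(nSubjects = 3, sleepTibMinutes = 240, seed = 5)
  for (s in 1:3) {
    night <- simulateSleepNight(cfg, s, "sham", eeg = FALSE)
    h <- night$hypnogram
    a <- scoreArchitecture(h)
    expect_lte(a$tst, a$tib)
    expect_equal(a$nremMinutes + a$remMinutes, a$tst)
    cyc <- cycles(detectCycles(h))
    expect_gt(nrow(cyc), 0)
    ends <- ifelse(is.na(cyc$remEnd), cyc$nremEnd, cyc$remEnd)
    if (nrow(cyc) > 1)
      expect_true(all(cyc$nremStart[-1] > ends[-nrow(cyc)]))
    totalMin <- sum(ends - cyc$nremStart + 1) / 2
    expect_lte(totalMin, a$tib)
  }
})

test_that("generator stage counts match the hypnogram exactly", {
  cfg <- simConfig(nSubjects = 1, sleepTibMinutes = 120, seed = 6)
  night <- simulateSleepNight(cfg, 1, "sham", eeg = FALSE)
  tab <- table(factor(stages(night$hypnogram),
                      c("W", "N1", "N2", "N3", "R")))
  expect_equal(as.numeric(night$truth$stageCounts), as.numeric(tab))
})

test_that("first-cycle NREM spectra use only NREM-staged epochs", {
  cfg <- simConfig(nSubjects = 1, sfreqSleep = 128, artifactRate = 0,
                   lineNoiseAmplitude = 0, seed = 7,
                   sleepTibMinutes = 30)
  stagesSeq <- c(rep("N2", 20), rep("W", 2), rep("N2", 20), rep("R", 12))
  night <- simulateSleepNight(cfg, 1, "sham", stages = stagesSeq)
  expect_equal(stages(night$hypnogram), stagesSeq)
  cyc <- detectCycles(night$hypnogram)
  fc <- firstCycleNremSpectra(night$recording, night$hypnogram, cyc,
                              preprocess = FALSE)
  expect_equal(fc$nEpochs, 40)   # the 2 W epochs inside the span excluded
  expect_s4_class(fc$bandPower, "BandPowerTable")
  expect_equal(length(fc$plv), 5)
  expect_s4_class(fc$plv$delta, "PLVMatrix")
})

test_that("deep-sleep delta exceeds wake delta under the 10x N3 gain", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 30, sfreqSleep = 128,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   couplingPairs = list(), seed = 8, sleepTibMinutes = 40)
  stagesSeq <- c(rep("N3", 40), rep("R", 12))
  night <- simulateSleepNight(cfg, 1, "active", stages = stagesSeq)
  cyc <- detectCycles(night$hypnogram)
  fc <- firstCycleNremSpectra(night$recording, night$hypnogram, cyc,
                              preprocess = FALSE)
  wake <- simulateWakeRecording(cfg, 1, "active", "T1")
  esW <- segmentAndReject(wake$recording, 5, Inf)
  bpW <- bandValues(bandPower(welchPsd(esW)))
  sleepDelta <- mean(bandValues(fc$bandPower)[, "delta"])
  wakeDelta <- mean(bpW[, "delta"])
  expect_gt(sleepDelta, 5 * wakeDelta)   # configured gain is 10x
})
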
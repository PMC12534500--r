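# Generator contracts: determinism, effect injection, artifact and
# coupling ground truth, power calibration.

test_that("generation is deterministic under (seed, subject, arm, timepoint)", {
  cfg <- simConfig(nSubjects = 2, wakeDuration = 10, seed = 11,
                   channelSet = c("F4", "O1", "Cz"))
  r1 <- simulateWakeRecording(cfg, 1, "active", "T3")
  r2 <- simulateWakeRecording(cfg, 1, "active", "T3")
  expect_identical(recData(r1$recording), recData(r2$recording))
  expect_identical(r1$truth, r2$truth)
  # different coordinates give different data
  r3 <- simulateWakeRecording(cfg, 2, "active", "T3")
  expect_false(identical(recData(r1$recording), recData(r3$recording)))
  n1 <- simulateSleepNight(cfg, 1, "sham", eeg = FALSE)
  n2 <- simulateSleepNight(cfg, 1, "sham", eeg = FALSE)
  expect_identical(stages(n1$hypnogram), stages(n2$hypnogram))
})

test_that("serialized recordings are byte-identical across reruns", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 5, seed = 12,
                   channelSet = c("F4", "O1"))
  f1 <- tempfile(); f2 <- tempfile()
  writeRecording(simulateWakeRecording(cfg, 1, "sham", "T1")$recording, f1)
  writeRecording(simulateWakeRecording(cfg, 1, "sham", "T1")$recording, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("a flat effect ramp makes active and sham arms equivalent", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 10, seed = 13,
                   activeEffectRamp = rep(1, 6),
                   channelSet = c("F4", "O1"))
  a <- simulateWakeRecording(cfg, 1, "active", "T6")
  s <- simulateWakeRecording(cfg, 1, "sham", "T6")
  expect_identical(a$truth$bandPower, s$truth$bandPower)
  expect_identical(a$truth$gains, s$truth$gains)
})

test_that("invalid arms, timepoints and configs are rejected by name", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 5,
                   channelSet = c("F4", "O1"))
  expect_error(simulateWakeRecording(cfg, 1, "placebo", "T1"), "arm")
  expect_error(simulateWakeRecording(cfg, 1, "active", "T7"), "timepoint")
  expect_error(simConfig(activeEffectRamp = c(1.1, 1, 1, 1, 1, 1)),
               "activeEffectRamp")
  expect_error(simConfig(activeEffectRamp = c(1, 1.2, 1.1, 1.3, 1.3, 1.3)),
               "non-decreasing")
  expect_error(simConfig(couplingPairs = list(
    list(a = "F4", b = "O1", band = "theta", strength = 1.2))),
    "coupling")
  expect_error(simConfig(bandPowerBaseline = c(delta = -1, theta = 1,
                                               alpha = 1, beta = 1,
                                               gamma = 1)),
               "positive")
})

test_that("a clean config stays under the artifact threshold", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 30, seed = 14,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   couplingPairs = list())
  sim <- simulateWakeRecording(cfg, 1, "sham", "T1")
  expect_lt(max(abs(recData(sim$recording))), 100)
  expect_equal(length(sim$truth$artifactEpochs), 0)
  # and with no line noise, 50 Hz carries no excess power
  es <- segmentAndReject(sim$recording, 5, 100)
  w <- welchPsd(es)
  at50 <- w$psd[1, w$freqs == 50]
  background <- mean(w$psd[1, w$freqs >= 40 & w$freqs < 48])
  expect_lt(at50, 5 * background)
})

test_that("every ground-truth artifact epoch is caught by the rejection rule", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 60, seed = 15,
                   artifactRate = 6)
  sim <- simulateWakeRecording(cfg, 1, "sham", "T1")
  expect_gt(length(sim$truth$artifactEpochs), 0)
  pre <- preprocessWake(sim$recording)
  es <- segmentAndReject(pre, 5, 100)
  expect_true(all(sim$truth$artifactEpochs %in% rejectedIndices(es)))
})

test_that("measured band power matches the configured values within 10%", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 300, seed = 1,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   couplingPairs = list())
  sim <- simulateWakeRecording(cfg, 1, "sham", "T1")
  es <- segmentAndReject(sim$recording, 5, Inf)
  bp <- bandValues(bandPower(welchPsd(es)))
  relErr <- abs(bp / sim$truth$bandPower - 1)
  expect_lt(max(relErr), 0.10)
})

test_that("the active ramp scales delta and theta as configured", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 120, seed = 16,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   couplingPairs = list(),
                   channelSet = c("F4", "O1", "Cz"))
  simT1 <- simulateWakeRecording(cfg, 1, "active", "T1")
  simT6 <- simulateWakeRecording(cfg, 1, "active", "T6")
  expect_equal(unname(simT6$truth$gains[c("delta", "theta")]),
               c(1.3, 1.3))
  bp1 <- bandValues(bandPower(welchPsd(
    segmentAndReject(simT1$recording, 5, Inf))))
  bp6 <- bandValues(bandPower(welchPsd(
    segmentAndReject(simT6$recording, 5, Inf))))
  rampRatio <- mean(bp6[, c("delta", "theta")] / bp1[, c("delta", "theta")])
  expect_lt(abs(rampRatio - 1.3), 0.13)
  flatRatio <- mean(bp6[, c("alpha", "beta", "gamma")] /
                      bp1[, c("alpha", "beta", "gamma")])
  expect_lt(abs(flatRatio - 1), 0.10)
})

test_that("estimated PLV rises monotonically with coupling strength", {
  plvAt <- function(strength) {
    cfg <- simConfig(nSubjects = 1, wakeDuration = 60, seed = 17,
                     artifactRate = 0, lineNoiseAmplitude = 0,
                     couplingPairs = list(list(a = "F4", b = "O1",
                                               band = "theta",
                                               strength = strength)))
    sim <- simulateWakeRecording(cfg, 1, "sham", "T1")
    es <- segmentAndReject(sim$recording, 5, Inf)
    plvValues(phaseLockingValue(es, eegBands()[2, ]))["F4", "O1"]
  }
  v <- vapply(c(0, 0.5, 1), plvAt, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("full-strength coupling of pure narrowband sources locks completely", {
  cfg <- simConfig(nSubjects = 1, wakeDuration = 30, seed = 18,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   bandPowerBaseline = c(delta = 1e-6, theta = 1.5,
                                         alpha = 1e-6, beta = 1e-6,
                                         gamma = 1e-6),
                   couplingPairs = list(list(a = "F4", b = "O1",
                                             band = "theta",
                                             strength = 1)))
  sim <- simulateWakeRecording(cfg, 1, "sham", "T1")
  es <- segmentAndReject(sim$recording, 5, Inf)
  v <- plvValues(phaseLockingValue(es, eegBands()[2, ]))
  expect_gt(v["F4", "O1"], 0.99)
})

test_that("forced hypnograms pass through and nights are reproducible", {
  cfg <- simConfig(nSubjects = 1, sfreqSleep = 128, seed = 19,
                   sleepTibMinutes = 31)
  forced <- c(rep("W", 10), rep("N2", 40), rep("R", 12))
  night <- simulateSleepNight(cfg, 1, "sham", stages = forced)
  expect_equal(stages(night$hypnogram), forced)
  night2 <- simulateSleepNight(cfg, 1, "sham", stages = forced)
  expect_identical(recData(night$recording), recData(night2$recording))
})
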
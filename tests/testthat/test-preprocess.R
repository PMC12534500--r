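# Preprocessing chain: referencing, filtering, segmentation, artifact
# rules, channel selection and exclusion.

test_that("notch removes a pure 50 Hz sinusoid by at least 40 dB", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  x <- rbind(20 * sin(2 * pi * 50 * t), 20 * cos(2 * pi * 50 * t))
  rec <- Recording(x, c("a", "b"), fs)
  out <- preprocessWake(rec, reference = FALSE)
  # drop filter edges before measuring
  core <- (2 * fs):(8 * fs)
  rmsIn <- sqrt(mean(x[1, core]^2))
  rmsOut <- sqrt(mean(recData(out)[1, core]^2))
  expect_gt(20 * log10(rmsIn / rmsOut), 40)
})

test_that("channel-wise constant offsets are eliminated", {
  fs <- 500
  n <- 30 * fs
  x <- matrix(c(rep(10, n), rep(-3, n), rep(7, n)), 3, byrow = TRUE)
  rec <- Recording(x, c("a", "b", "c"), fs)
  out <- preprocessWake(rec)
  core <- (10 * fs):(20 * fs)   # away from filter settle-in
  expect_lt(max(abs(recData(out)[, core])), 1e-4)
})

test_that("white noise keeps less than 1% of its power outside 1-60 Hz", {
  fs <- 1000
  set.seed(11)
  rec <- Recording(matrix(rnorm(60 * fs), 1), "Fz", fs)
  out <- preprocessWake(rec, notchFreq = NULL, reference = FALSE)
  es <- epochsFromMatrix(recData(out), "Fz", fs, 5)
  w <- welchPsd(es)
  inBand <- w$freqs >= 1 & w$freqs <= 60
  # exclude the transition neighbourhoods of the band edges
  stopBand <- w$freqs < 0.5 | w$freqs > 75
  pIn <- sum(w$psd[1, inBand]) * w$freqResolution
  pOut <- sum(w$psd[1, stopBand]) * w$freqResolution
  expect_lt(pOut / pIn, 0.01)
})

test_that("common-average-referenced output has zero cross-channel mean", {
  set.seed(12)
  rec <- Recording(matrix(rnorm(5 * 2000), 5), paste0("c", 1:5), 200)
  out <- commonAverageReference(rec)
  expect_lt(max(abs(colMeans(recData(out)))), 1e-10)
})

test_that("preprocessing rejects sampling rates below the Nyquist need", {
  rec <- Recording(matrix(rnorm(1000), 1), "Fz", 100)
  expect_error(preprocessWake(rec), "Nyquist")
})

test_that("segmentation arithmetic and the strict threshold rule", {
  fs <- 200
  x <- matrix(rnorm(2 * 300 * fs, sd = 5), 2)
  rec <- Recording(x, c("a", "b"), fs)
  es <- segmentAndReject(rec, 5, 100)
  expect_equal(length(keptIndices(es)), 60)
  expect_equal(length(rejectedIndices(es)), 0)
  # one +101 sample in epoch 7 rejects epoch 7 only
  x2 <- x
  x2[1, 6 * 5 * fs + 10] <- 101
  es2 <- segmentAndReject(Recording(x2, c("a", "b"), fs), 5, 100)
  expect_equal(rejectedIndices(es2), 7L)
  # exactly at the threshold is kept (strict inequality)
  x3 <- x
  x3[1, 10] <- 100
  es3 <- segmentAndReject(Recording(x3, c("a", "b"), fs), 5, 100)
  expect_equal(length(rejectedIndices(es3)), 0)
  # trailing partial segment is discarded
  es4 <- segmentAndReject(Recording(x[, 1:(7.5 * fs)], c("a", "b"), fs),
                          5, 100)
  expect_equal(dim(es4@epochs)[1], 1)
})

test_that("rejection is idempotent on the kept epochs", {
  set.seed(13)
  fs <- 200
  x <- matrix(rnorm(2 * 100 * fs, sd = 30), 2)
  x[1, sample(ncol(x), 20)] <- 150
  es <- segmentAndReject(Recording(x, c("a", "b"), fs), 5, 100)
  keptData <- do.call(cbind, lapply(keptIndices(es), function(e)
    es@epochs[e, , , drop = FALSE][1, , ]))
  es2 <- segmentAndReject(Recording(keptData, c("a", "b"), fs), 5, 100)
  expect_equal(length(rejectedIndices(es2)), 0)
})

test_that("channel selection preserves the requested order and errors on unknowns", {
  set.seed(14)
  labs <- c(wakeMontage(), paste0("X", 1:43))
  rec <- Recording(matrix(rnorm(64 * 1000), 64), labs, 1000)
  sel <- selectChannels(rec, wakeMontage())
  expect_equal(channelNames(sel), wakeMontage())
  expect_equal(nChannels(sel), 21)
  expect_equal(recData(selectChannels(rec, labs)), recData(rec))
  expect_error(selectChannels(rec, c("Fz", "XX")), "XX")
})

test_that("the >50% artifact rule excludes channels and revives their epochs", {
  fs <- 200
  nEp <- 10
  x <- matrix(rnorm(3 * nEp * 5 * fs, sd = 5), 3)
  # channel c bad in 6 of 10 epochs (60%)
  for (e in 1:6) x[3, ((e - 1) * 5 * fs) + 5] <- 200
  es <- segmentAndReject(Recording(x, c("a", "b", "c"), fs), 5, 100)
  expect_equal(length(rejectedIndices(es)), 6)
  es2 <- excludeBadChannels(es, 0.5)
  expect_equal(excludedChannels(es2), "c")
  expect_equal(length(keptIndices(es2)), 10)
  # exactly 50% is retained (strictly-greater rule)
  x3 <- matrix(rnorm(2 * nEp * 5 * fs, sd = 5), 2)
  for (e in 1:5) x3[2, ((e - 1) * 5 * fs) + 5] <- 200
  es3 <- segmentAndReject(Recording(x3, c("a", "b"), fs), 5, 100)
  es4 <- excludeBadChannels(es3, 0.5)
  expect_equal(length(excludedChannels(es4)), 0)
  # all clean: identity
  es5 <- segmentAndReject(Recording(matrix(rnorm(2 * 2000), 2),
                                    c("a", "b"), fs), 5, 100)
  expect_identical(excludeBadChannels(es5), es5)
})
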
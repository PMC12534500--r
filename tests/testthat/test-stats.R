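# Paired contrasts with FDR, repeated-measures ANOVA, correlation,
# a priori sample size.

test_that("identical conditions yield nothing significant", {
  set.seed(41)
  a <- matrix(rnorm(10 * 4), 10, dimnames = list(NULL, paste0("e", 1:4)))
  # exactly identical: zero within-pair variance everywhere, so every
  # unit is degenerate (excluded, not assigned p = 1) and nothing passes
  expect_message(res <- pairedTFdr(a, a), "degenerate")
  expect_true(all(res$degenerate))
  expect_false(any(res$significant))
})

test_that("BH adjustment equals the hand step-up definition", {
  # worked example: {0.01, 0.02, 0.03, 0.04} over 4 units -> all q = 0.04
  expect_equal(bruteForceBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    q <- p.adjust(p, "BH")
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("paired t equals one-sample t on within-pair differences", {
  set.seed(43)
  a <- matrix(rnorm(12 * 3), 12, dimnames = list(NULL, paste0("e", 1:3)))
  b <- a + matrix(rnorm(36, 0.5), 12)
  res <- pairedTFdr(a, b)
  for (j in 1:3) {
    tt <- t.test(b[, j] - a[, j])
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-12)
    expect_equal(res$df[j], 11)
  }
})

test_that("zero-variance units are excluded from the FDR family", {
  set.seed(44)
  a <- matrix(rnorm(8 * 3), 8, dimnames = list(NULL, c("e1", "e2", "e3")))
  b <- a + matrix(rnorm(24, 1), 8)
  b[, 2] <- a[, 2] + 5   # constant difference: zero within-pair variance
  expect_message(res <- pairedTFdr(a, b), "degenerate")
  expect_true(res$degenerate[2])
  expect_true(is.na(res$q[2]))
  expect_equal(res$q[c(1, 3)], p.adjust(res$p[c(1, 3)], "BH"))
})

test_that("rm-ANOVA on constant data gives F = 0, p = 1", {
  d <- expand.grid(subject = 1:4, arm = c("active", "sham"),
                   time = paste0("T", 1:3))
  d$value <- 5
  res <- rmAnova(d)
  expect_equal(res$F, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("rm-ANOVA F matches explicit sums-of-squares arithmetic on a 2x2", {
  set.seed(45)
  d <- expand.grid(subject = factor(1:3), arm = c("a1", "a2"),
                   time = c("t1", "t2"))
  d$value <- rnorm(nrow(d), mean = 2) +
    ifelse(d$arm == "a2", 0.8, 0) + ifelse(d$time == "t2", -0.5, 0) +
    ifelse(d$arm == "a2" & d$time == "t2", 0.4, 0)
  res <- rmAnova(d)
  # brute-force decomposition by direct summation
  y <- d$value
  gm <- mean(y)
  mS <- tapply(y, d$subject, mean)
  mA <- tapply(y, d$arm, mean)
  mT <- tapply(y, d$time, mean)
  mSA <- tapply(y, interaction(d$subject, d$arm), mean)
  mST <- tapply(y, interaction(d$subject, d$time), mean)
  mAT <- tapply(y, interaction(d$arm, d$time), mean)
  nS <- 3; nA <- 2; nT <- 2
  ssA <- nS * nT * sum((mA - gm)^2)
  ssT <- nS * nA * sum((mT - gm)^2)
  ssSA <- nT * sum((mSA - rep(mS, nA) -
                      rep(mA, each = nS) + gm)^2)
  ssST <- nA * sum((mST - rep(mS, nT) -
                      rep(mT, each = nS) + gm)^2)
  ssAT <- nS * sum((mAT - rep(mA, nT) -
                      rep(mT, each = nA) + gm)^2)
  ssTot <- sum((y - gm)^2)
  ssS <- nA * nT * sum((mS - gm)^2)
  ssSAT <- ssTot - ssS - ssA - ssT - ssSA - ssST - ssAT
  fA <- (ssA / (nA - 1)) / (ssSA / ((nS - 1) * (nA - 1)))
  fT <- (ssT / (nT - 1)) / (ssST / ((nS - 1) * (nT - 1)))
  fAT <- (ssAT / ((nA - 1) * (nT - 1))) /
    (ssSAT / ((nS - 1) * (nA - 1) * (nT - 1)))
  expect_equal(res$F[res$effect == "intervention"], fA, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "time"], fT, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "interaction"], fAT, tolerance = 1e-8)
})

test_that("pure subject offsets produce no condition effects", {
  d <- expand.grid(subject = 1:5, arm = c("a1", "a2"),
                   time = paste0("T", 1:3))
  d$value <- as.numeric(d$subject) * 3
  res <- rmAnova(d)
  expect_true(all(res$F < 1e-10))
})

test_that("two-level time reduces the ANOVA to the paired t (F = t^2)", {
  set.seed(46)
  n <- 8
  y1 <- rnorm(n); y2 <- rnorm(n, 0.7)
  # duplicate the same data in both arms: time effect collapses to a
  # one-way within comparison
  d <- rbind(
    data.frame(subject = 1:n, arm = "a1", time = "T1", value = y1),
    data.frame(subject = 1:n, arm = "a1", time = "T2", value = y2),
    data.frame(subject = 1:n, arm = "a2", time = "T1", value = y1),
    data.frame(subject = 1:n, arm = "a2", time = "T2", value = y2))
  res <- rmAnova(d)
  tt <- t.test(y2 - y1)
  expect_equal(res$F[res$effect == "time"], unname(tt$statistic)^2,
               tolerance = 1e-8)
})

test_that("rm-ANOVA refuses incomplete designs", {
  d <- expand.grid(subject = 1:4, arm = c("a1", "a2"),
                   time = c("T1", "T2"))
  d$value <- rnorm(nrow(d))
  expect_error(rmAnova(d[-1, ]), "incomplete|unbalanced")
})

test_that("Pearson correlation recovers exact linear association", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1)
  ct <- wakeSleepCorrelation(x, 2 * x + 1)
  expect_equal(ct$r, 1.0)
  expect_equal(ct$n, 5)
  expect_error(wakeSleepCorrelation(x, rep(1, 5)), "zero variance")
})

test_that("the null correlation test keeps its nominal size", {
  set.seed(47)
  reps <- 1000
  p <- vapply(seq_len(reps), function(i)
    wakeSleepCorrelation(rnorm(25), rnorm(25))$p, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)   # Monte-Carlo margin at 1000 reps
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("paired-t sample size matches the noncentral-t computation", {
  expect_equal(pairedTSampleSize(0.5, 0.05, 0.9), 44)
  # independent oracle: base R power curve over candidate n
  powers <- vapply(2:100, function(n)
    power.t.test(n = n, delta = 0.5, sd = 1, sig.level = 0.05,
                 type = "one.sample", alternative = "two.sided")$power,
    numeric(1))
  expect_equal((2:100)[which(powers >= 0.9)[1]], 44)
  # monotone non-increasing in effect size, clamped at tiny n for huge d
  ns <- vapply(c(0.3, 0.5, 0.8, 1.5, 3), pairedTSampleSize, numeric(1),
               alpha = 0.05, power = 0.9)
  expect_true(all(diff(ns) <= 0))
  expect_lte(ns[length(ns)], 4)
  expect_error(pairedTSampleSize(0.5, 0.2, 0.1), "unattainable")
})

test_that("wake theta change correlates with first-cycle sleep theta when the generator couples them", {
  cfg <- simConfig(nSubjects = 10, wakeDuration = 30, sfreqWake = 250,
                   sfreqSleep = 128, sleepTibMinutes = 40,
                   artifactRate = 0, lineNoiseAmplitude = 0,
                   couplingPairs = list(), subjectVariability = 0.6,
                   channelSet = c("F4", "O1", "Cz"), seed = 49)
  wakeChange <- sleepTheta <- numeric(10)
  for (s in 1:10) {
    bpAt <- function(tp) {
      sim <- simulateWakeRecording(cfg, s, "active", tp)
      bandValues(bandPower(welchPsd(
        segmentAndReject(sim$recording, 5, Inf))))["F4", "theta"]
    }
    wakeChange[s] <- bpAt("T6") - bpAt("T1")
    night <- simulateSleepNight(cfg, s, "active")
    fc <- firstCycleNremSpectra(night$recording, night$hypnogram,
                                detectCycles(night$hypnogram),
                                preprocess = FALSE)
    sleepTheta[s] <- mean(bandValues(fc$bandPower)[, "theta"])
  }
  ct <- wakeSleepCorrelation(wakeChange, sleepTheta)
  expect_gt(ct$r, 0)
  expect_lt(ct$p, 0.05)
})

test_that("per-family false-positive electrode rate is controlled under the null", {
  set.seed(48)
  nStudies <- 200
  fpProp <- vapply(seq_len(nStudies), function(i) {
    a <- matrix(rnorm(20 * 21), 20)
    b <- matrix(rnorm(20 * 21), 20)
    colnames(a) <- colnames(b) <- paste0("e", 1:21)
    mean(pairedTFdr(a, b)$significant)
  }, numeric(1))
  expect_lt(mean(fpProp), 0.05 + 0.02)
})
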
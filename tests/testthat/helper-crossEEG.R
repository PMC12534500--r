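# Shared fixtures: small simulation configs and hand-built containers.

# Clean few-channel config without nuisance signals, for calibration and
# spectral checks.
cleanConfig <- function(channels = c("Fz", "Cz", "Pz"), duration = 60,
                        seed = 1, ...) {
  simConfig(nSubjects = 2, wakeDuration = duration, channelSet = channels,
            artifactRate = 0, lineNoiseAmplitude = 0,
            couplingPairs = list(), seed = seed, ...)
}

# EpochSet built directly from a channels x samples matrix (no rejection).
epochsFromMatrix <- function(data, channelNames, sfreq, epochLength) {
  rec <- Recording(data, channelNames, sfreq)
  segmentAndReject(rec, epochLength, threshold = Inf)
}

# Brute-force graph metrics on small weighted graphs, by direct
# enumeration: triple sums for clustering, Floyd-Warshall over inverse
# weights for distances, exhaustive neighbour subgraphs for local
# efficiency. Independent of the package's igraph-based implementation.
bruteForceMetrics <- function(w) {
  diag(w) <- 0
  n <- nrow(w)
  mx <- max(w)
  wh <- if (mx > 0) (w / mx)^(1 / 3) else w
  k <- rowSums(w > 0)
  cc <- numeric(n)
  for (i in 1:n) {
    if (k[i] < 2) next
    s <- 0
    for (j in 1:n) for (h in 1:n)
      if (j != i && h != i && j != h)
        s <- s + wh[i, j] * wh[i, h] * wh[j, h]
    cc[i] <- s / (k[i] * (k[i] - 1))
  }
  fw <- function(wm) {
    m <- nrow(wm)
    D <- matrix(Inf, m, m)
    D[wm > 0] <- 1 / wm[wm > 0]
    diag(D) <- 0
    for (mid in seq_len(m)) for (a in seq_len(m)) for (b in seq_len(m))
      if (D[a, mid] + D[mid, b] < D[a, b])
        D[a, b] <- D[a, mid] + D[mid, b]
    D
  }
  D <- fw(w)
  off <- D[row(D) != col(D)]
  cpl <- mean(off[is.finite(off)])
  ge <- mean(ifelse(is.finite(off), 1 / off, 0))
  wn <- if (mx > 0) w / mx else w
  le <- numeric(n)
  for (i in 1:n) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) next
    Ds <- fw(wn[nb, nb, drop = FALSE])
    s <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a != b && is.finite(Ds[a, b]) && Ds[a, b] > 0)
        s <- s + (wn[i, nb[a]] * wn[i, nb[b]] / Ds[a, b])^(1 / 3)
    le[i] <- s / (length(nb) * (length(nb) - 1))
  }
  list(cc = cc, meanCc = mean(cc), cpl = cpl, ge = ge,
       le = le, meanLe = mean(le))
}

# Random symmetric weighted graph with some zero edges.
randomWeightedGraph <- function(n, pZero = 0.3) {
  w <- matrix(stats::runif(n * n), n)
  w[stats::runif(n * n) < pZero] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Hand step-up Benjamini-Hochberg: q_i = min_{k >= rank_i} p_(k) m / k.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
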
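# Shared signal-processing primitives: zero-phase IIR filtering, notch
# design, analytic-signal phase, Hamming window, substream seeding.

hammingWindow <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# 4th-order Butterworth band-pass; edges in Hz. Realized as a cascade of
# a 4th-order high-pass at flo and a 4th-order low-pass at fhi: the
# direct transfer-function band-pass is numerically unstable when the
# normalized band is narrow (e.g. 1-4 Hz at 1000 Hz sampling), while the
# cascade keeps the same -3 dB edges and is stable. Applied
# forward-backward (zero net phase) everywhere in the package.
designBandpass <- function(flo, fhi, sfreq) {
  nyq <- sfreq / 2
  if (fhi >= nyq)
    stop(sprintf(
      "upper band edge %g Hz violates the Nyquist constraint (sfreq %g Hz, Nyquist %g Hz)",
      fhi, sfreq, nyq))
  if (flo <= 0 || flo >= fhi)
    stop(sprintf("invalid band edges [%g, %g] Hz", flo, fhi))
  structure(list(hp = signal::butter(4, flo / nyq, type = "high"),
                 lp = signal::butter(4, fhi / nyq, type = "low")),
            class = "bandpassCascade")
}

# Forward-backward application of a single Arma filter or a cascade.
zeroPhaseFilter <- function(filt, x) {
  if (inherits(filt, "bandpassCascade"))
    signal::filtfilt(filt$lp, signal::filtfilt(filt$hp, x))
  else
    signal::filtfilt(filt, x)
}

# 2nd-order IIR notch (biquad), quality factor q; standard audio-EQ cookbook
# coefficients, zeros on the unit circle at the notch frequency.
designNotch <- function(freq, sfreq, q = 30) {
  w0 <- 2 * pi * freq / sfreq
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

# Forward-backward filtering of the rows of a channels x samples matrix.
filtfiltRows <- function(filt, x) {
  t(apply(x, 1, function(row) zeroPhaseFilter(filt, row)))
}

# Analytic signal via FFT: zero the negative frequencies, double the
# positive ones, keep DC (and Nyquist for even n) untouched.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Squared-magnitude response |H(f)|^2 of a filter applied forward-backward
# equals |H|^4 of the single pass; mean of |H|^4 over the band's frequency
# bins calibrates band-limited noise generation.
meanBandResponse <- function(filt, flo, fhi, sfreq, n = 4096) {
  if (inherits(filt, "bandpassCascade")) {
    f1 <- signal::freqz(filt$hp, n = n, Fs = sfreq)
    f2 <- signal::freqz(filt$lp, n = n, Fs = sfreq)
    f <- f1$f; h <- f1$h * f2$h
  } else {
    fr <- signal::freqz(filt, n = n, Fs = sfreq)
    f <- fr$f; h <- fr$h
  }
  inband <- f >= flo & f < fhi
  mean(Mod(h[inband])^4)
}

# Deterministic substream seed below 2^31 from a base seed and a small set
# of integer coordinates (documented counter scheme: mixed-radix offsets
# with fixed prime multipliers).
substreamSeed <- function(seed, ...) {
  coords <- c(...)
  primes <- c(1000003, 7919, 104729, 31337)
  s <- as.double(seed %% 2147483647)
  for (i in seq_along(coords))
    s <- (s + primes[((i - 1) %% length(primes)) + 1] *
            (as.double(coords[i]) + 1)) %% 2147483647
  as.integer(s)
}

stopNoData <- function(what) {
  stop(sprintf("no analyzable data: %s", what), call. = FALSE)
}
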
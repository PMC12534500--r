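---
title: "Wake and sleep EEG analysis of a crossover neurostimulation study"
author: "crossEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wake and sleep EEG analysis of a crossover neurostimulation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossEEG)
```

# Overview

`crossEEG` implements the analysis chain of a counterbalanced active/sham
crossover study of continuous theta-burst stimulation (cTBS) over the right
dorsolateral prefrontal cortex, measured by eyes-closed resting-state EEG at
six timepoints (before and after each of three stimulation sessions) during
wakefulness, and by overnight polysomnography afterwards. The chain is:

1. **Preprocessing** — common-average reference, 1–60 Hz band-pass, 50 Hz
   notch, fixed-length segmentation (5 s wake, 30 s sleep), ±100 µV
   amplitude-artifact rejection, selection of a sparse 21-channel 10–20
   montage (volume-conduction mitigation by electrode sparsification).
2. **Spectral power** — Welch's averaged modified periodogram (Hamming
   window, one whole epoch per segment, no overlap), mean PSD in the five
   canonical bands: delta 1–4, theta 5–8, alpha 8–13, beta 13–30,
   gamma 30–60 Hz.
3. **Connectivity** — phase-locking value (PLV) between all electrode
   pairs per band, from band-passed, Hilbert-derived instantaneous phases,
   giving a weighted 21 × 21 adjacency matrix.
4. **Network metrics** — weighted clustering coefficient (CC),
   characteristic path length (CPL), global efficiency (GE) and local
   efficiency (LE) of the *unthresholded* PLV network.
5. **Statistics** — paired two-tailed t-tests with Benjamini–Hochberg FDR
   across electrodes/edges, two-way repeated-measures ANOVA
   (intervention × time), a-priori paired-t sample size via the noncentral
   t distribution, and the Pearson correlation between the wake
   band-power change (ΔPSD = PSD at T6 − PSD at T1, z-scored across
   subjects within band at electrode F4) and first-sleep-cycle NREM power.
6. **Sleep** — architecture summary (TIB, TST, SE, SL, WASO, NREM, REM
   minutes), NREM–REM cycle detection by the Feinberg–Floyd criteria, and
   PSD/PLV of the first cycle's NREM period.

Because no clinical recordings ship with the package, a synthetic-data
generator reproduces the whole design with known ground truth, so every
stage can be validated end to end.

# The synthetic generator

`simConfig()` fixes the study conditions; `simulateWakeRecording()` and
`simulateSleepNight()` draw deterministic recordings from them.

**Band-limited noise.** Each band is realized as Gaussian noise
band-limited in the spectral domain with the same half-open band edges
(`flo <= f < fhi`) the spectral module uses, so generator and analyzer
agree exactly on band definitions. Two calibration refinements make the
configured value recoverable:

* *Exact-power synthesis*: each realization is rescaled so its in-band
  power equals its expectation, removing the chi-square amplitude
  fluctuation of the draw while keeping the spectral shape random.
* *Window-retention compensation*: a Hamming-windowed periodogram of a
  brick-wall band spectrum smears edge-bin energy out of the band (about
  9 % for a 3 Hz band at 5 s segments). The generator scales amplitudes by
  the analytically computed retention factor of the analyzing
  segmentation (5 s wake, 30 s sleep), so that *measured* Welch band
  power matches the configured value. On artifact-free 300 s recordings
  the per-channel recovery error stays inside 10 %.

**Injected effects.** The active arm multiplies delta and theta power by a
non-decreasing six-element gain ramp (default reaching +30 % at T6; the
first element is pinned to 1 so baseline T1 is unmodified). The study the
design mirrors did not report effect sizes for its band-power increases,
so the ramp is a free parameter of the generator, not an estimate. An
optional lognormal per-subject factor (`subjectVariability`) modulates
the theta effect identically during wake and sleep, which induces the
wake→sleep theta coupling the correlation analysis is meant to detect.

**Coupling.** A configured pair shares a common narrowband source mixed
into both channels: `sqrt(s) * shared + sqrt(1 - s) * own`, with
channel-specific independent noise. The strength `s` in [0, 1] maps
monotonically — not identically — onto estimated PLV, because the phase
estimate of the band-passed mixture is also perturbed by the channel's
other bands; tests therefore assert monotone recovery (and perfect
locking when the other bands are negligible), not numeric equality.

**Artifacts and line noise.** Artifacts are 200 ms raised-cosine
transients of ±150 µV placed fully inside one analysis epoch on one
channel, so they unambiguously cross the ±100 µV rule and the flagged
epoch is exactly the affected one; 50 Hz line noise is added per channel
with a random phase (a common phase would vanish under the
common-average reference and leave nothing for the notch to do).

**Seeding.** One base seed expands into per-(subject, arm, timepoint)
substreams by a fixed mixed-radix counter scheme with prime multipliers
(`substreamSeed`), so any single recording can be regenerated
independently and reruns are byte-identical after serialization.

**What the generator does not emulate**: 1/f (aperiodic) background,
ocular/muscle artifact morphology, TMS pulse artifacts, non-stationarity
within a stage, and volume-conduction mixing beyond the configured
coupling. Passing tests therefore demonstrate correctness of the
estimators and inferential machinery under the stated signal model, not
robustness to every property of clinical EEG.

# Numerical choices

* **Filters.** The band-pass is a 4th-order Butterworth realized as a
  high-pass/low-pass cascade: the direct transfer-function band-pass is
  numerically unstable at narrow normalized bands (1–4 Hz at 1000 Hz
  sampling), while the cascade keeps the same −3 dB edges and is stable.
  The notch is a 2nd-order IIR biquad with quality 30. Every filter is
  applied forward–backward (zero net phase) — essential ahead of phase
  estimation.
* **Welch normalization** is density-scaled so the PSD of unit-variance
  white noise integrates to 1 over [0, Nyquist]; one-sided with interior
  bins doubled; frequency resolution 1/epoch length. Band power is the
  *mean* PSD in band (µV²/Hz), not the integral — comparisons are always
  within band, so the choice is inert, but it is pinned.
* **Band edges** follow the half-open convention `flo <= f < fhi`; the
  8 Hz bin belongs to alpha, and the 4–5 Hz gap between delta and theta
  is kept as configured (those bins belong to no band). The theta lower
  edge is a parameter (`eegBands(thetaLow = )`) for users who prefer a
  contiguous 4 Hz boundary.
* **Phase/PLV.** Phase comes from the analytic signal (FFT Hilbert
  transform) of the band-passed epoch; 10 % of samples at each epoch end
  are excluded from time averages (filter and transform edge effects).
  PLV per pair is the modulus of the time-averaged unit phasor of the
  phase difference, computed per epoch and then averaged across epochs
  (mean of moduli, not modulus of the grand mean) — it respects the
  epoched structure and is pinned for determinism. Note that for
  narrowband signals the finite-T null PLV is far above the iid-phase
  value (phases decorrelate slowly), so uncoupled-pair baselines must be
  estimated by simulation at matched epoch length and count; the
  acceptance analysis does exactly that.
* **Graph metrics.** Weighted CC uses the Onnela geometric-mean
  formulation on weights normalized by the off-diagonal maximum (the
  brain-connectivity-toolbox default); connection lengths are inverse
  weights; CPL averages Dijkstra distances over connected ordered pairs
  (disconnected pairs are counted and excluded — PLV graphs are almost
  surely complete, so this is a degenerate-input safeguard); GE averages
  inverse distances with disconnected pairs contributing 0; LE follows
  the Rubinov–Sporns weighted variant on the neighbour-induced subgraph.
  Self-loops (unit PLV diagonal) are removed before all graph
  computations, and no thresholding is applied anywhere.
* **Statistics.** FDR families are one band × one comparison across its
  21 electrodes or 210 edges (matching per-panel reporting); units with
  zero within-pair variance are excluded from the family and logged, not
  assigned p = 1. The repeated-measures ANOVA tests each within-subject
  effect against its own subject × effect stratum; sphericity is
  uncorrected by default with Greenhouse–Geisser optionally available.
  z-scores use the population (n-denominator) SD, pinned for test
  determinism. Statistics operate on raw band power; the Pearson
  correlation is the default with Spearman by flag.
* **Sleep rules.** Feinberg–Floyd parameters are pinned at NREM ≥ 15 min
  and REM ≥ 5 min with the first REM period exempt; interruptions (wake,
  or REM runs too short to qualify) shorter than 5 min do not split an
  NREM period; a trailing REM-less NREM period forms an incomplete final
  cycle only on request. All four are parameters of `detectCycles()` —
  the classical criteria leave them open, so the defaults are disclosed
  package choices. WASO counts wake from sleep onset to lights-on with
  no final-awakening trimming. The strict inequalities "> 100 µV" and
  "> 50 %" are implemented as stated.
* **Boundary conventions.** Trailing partial segments are discarded,
  never padded; channel selection precedes referencing (the two do not
  commute, and the reference is computed over the analysis montage);
  the amplitude rule is applied to the filtered, re-referenced signal.

# Open design points, resolved

* Whether the ±100 µV rule was applied per channel or on an any-channel
  basis is unstated in the source protocol: wake rejection is
  any-channel at the epoch level, while per-channel bookkeeping is kept
  throughout because the sleep pipeline's "> 50 % artifact time" channel
  exclusion requires it.
* Whether PLV was averaged across epochs or computed on concatenated
  epochs is unstated; per-epoch averaging is implementation-defined here.
* The exact weighted local-efficiency variant differs between toolbox
  versions; the Rubinov–Sporns formulation is pinned and disclosed.
* EDF input/output is provided by a minimal built-in reader/writer
  (16-bit continuous EDF, physical units µV) covering the subset of the
  format the package produces and consumes.

# Problem sizes

Analyses in the test-suite and acceptance script run at deliberately
modest sizes chosen to exercise every code path with comfortable
statistical margins: the effect-recovery study uses the full 21-channel
montage with n = 20 subjects and 60 s recordings per timepoint (twelve
5-s epochs give a band-power SD of a few percent, so a +30 % effect is
detected with near-certain power while sham false positives stay at the
FDR's nominal level); calibration checks use the full 300 s duration;
sleep analyses use 40–240 min nights. The generator defaults (300 s wake
recordings, 480 min nights, 1000/512 Hz sampling) reproduce the full
study geometry.

# Limitations

The package analyzes what the design prescribes and no more: no
multitaper or wavelet spectra, no aperiodic decomposition, no
leakage-corrected connectivity (wPLI, imaginary coherence), no
small-world/modularity/MST graph analyses, no automatic sleep staging,
no resampling between the wake (1000 Hz) and sleep (512 Hz) streams, and
no source-space modelling. Reported clinical findings of the motivating
study (which rest on unreleased patient data) are not reproduction
targets; the package's claims are about the correctness of its
estimators and inference on data with known ground truth.
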
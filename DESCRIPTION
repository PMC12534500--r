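Package: crossEEG
Title: Wake and Sleep EEG Spectral Power, Phase-Locking Networks and
    Crossover Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for crossover neurostimulation EEG studies:
    band-resolved Welch power spectral density, phase-locking-value (PLV)
    connectivity networks, weighted graph metrics (clustering coefficient,
    characteristic path length, global and local efficiency), paired
    contrasts with false-discovery-rate correction, two-way repeated-measures
    ANOVA, a priori paired-t sample size, NREM-REM sleep-cycle segmentation
    by the Feinberg-Floyd criteria, and first-sleep-cycle spectral analysis.
    Includes a synthetic-data generator that reproduces a six-timepoint
    active/sham crossover design with controllable band power, inter-channel
    phase coupling, amplitude artifacts and line noise, so every analysis
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
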
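Package: ephysuite
Title: Rodent EEG Sleep Staging, Spike-Train Detection and HD-MEA Network
    Burst Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in-vivo wireless telemetry EEG/EMG
    recordings and in-vitro high-density microelectrode array (HD-MEA)
    spike rasters. Provides epoch-wise power spectral density with Hamming
    windowing and 2 Hz spectral rebinning, named band powers,
    threshold-based epileptiform spike and spike-train detection,
    rule-based four-stage sleep scoring from delta, theta:delta, EMG and
    accelerometer features, and network-burst detection by Gaussian
    convolution of pooled spike rasters with burst-level metrics
    (inter-burst interval, spikes per burst, burst duration). Includes a
    seeded synthetic-data generator (Markov sleep-state EEG/EMG/activity
    sessions and Poisson MEA rasters with planted network bursts and
    configurable genotype effects) so every stage of the pipeline can be
    validated against known ground truth, plus a genotype-comparison
    statistics layer (pooled t-tests, two-way repeated-measures ANOVA with
    Sidak post hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'edf.R'
    'eeg-events.R'
    'ephysuite-package.R'
    'group-stats.R'
    'mea.R'
    'spectral.R'
    'sleep-staging.R'
    'signal-io.R'
    'pipeline.R'
    'synth-noise.R'
    'synth-eeg.R'
    'synth-mea.R'
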
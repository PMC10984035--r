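---
title: "Methods: EEG sleep scoring, spike trains and HD-MEA network bursts"
author: "ephysuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG sleep scoring, spike trains and HD-MEA network bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysuite)
```

This vignette is the package's account of its own methods: the models
and rules it implements, the choices made where the design was open,
the calibration of the synthetic generators, and the limits of what the
shipped validation demonstrates.

## Signal model and I/O

A session is a `Recording`: EEG and EMG in microvolts at a common rate
(500 Hz in the telemetry setting, 0.1–100 Hz bandpass), an
accelerometer-derived activity channel in arbitrary units (200 Hz), a
genotype label and a duration. EDF is the canonical on-disk format
(16-bit, one data record per second); a tab-separated text layout is
provided when lossless float storage is wanted, since EDF quantizes to
one part in 65,535 of the channel range. An absent activity channel is
read as constant zero, which simply disables the activity rule in
staging rather than failing.

Time is seconds from session start; every epoching operation uses
half-open windows $[kL, (k+1)L)$ and discards a trailing partial epoch.

**Artifacts.** An epoch is artifact if |EEG| exceeds 0.2 mV or |EMG|
exceeds 1 mV anywhere within it. Masking is epoch-granular because all
downstream consumers (staging, band averaging) are epoch-granular; the
window over which the published levels were applied is not specified
anywhere we could find, so per-epoch application is our declared
choice. Spike detection deliberately ignores the mask: the spike
amplitude threshold (200 μV) *equals* the EEG artifact level, so
masking first would delete every detectable spike. A recording system
reporting abundant spikes cannot have rejected artifacts before
detecting them.

## Power spectral density

Each epoch is mean-removed, Hamming-windowed, and transformed with an
FFT; the one-sided periodogram is normalized as a density,

$$P(f_k) = \frac{2\,|X_k|^2}{f_s \sum_n w_n^2},$$

so that the rectangle-rule integral of $P$ equals the variance of the
windowed signal divided by the window mean-square (Parseval in the
density convention; the discarded DC bin contributes only the windowed
residual mean). No overlap is used between epochs and detrending is
mean removal only — the acquisition pipeline we emulate states neither,
and these are the simplest defensible defaults.

The native resolution of a 30 s epoch is 1/30 Hz. The published
description of the commercial analysis mentions finer early frequency
increments that cannot be reproduced from a 30 s window; since what is
ultimately reported is a 2 Hz-binned spectrum, we compute at native
resolution and rebin into 2 Hz segments (bin = mean density of member
frequencies, reported at the bin centre; a 0–50 Hz spectrum gives 25
segments). Band powers integrate the native grid over $[lo, hi)$.

**Theta ambiguity.** The band table ships two theta presets: 4–8 Hz
(the figure-legend convention, our default) and 5–9 Hz (the alternative
that appears in methods text of the same literature). They differ, and
nothing in the source material resolves the intent, so both are
available via `eegBands(theta = "alt")` and all band edges are
configurable.

## Spikes and spike trains

A spike is a maximal run of consecutive samples with $|x| > 200\,\mu V$
("absolute threshold" is read as either polarity crossing), accepted if
the run lasts 1–200 ms. Duration is time above threshold — the
reference level for duration is otherwise undefined — and events are
disjoint by construction.

Trains are greedy left-to-right chains on onsets: extend while the next
gap lies in $[0.05, 0.5]$ s; emit when the chain has ≥ 3 spikes and
spans ≥ 1 s. Two interpretive choices are config-switchable:

- a gap *shorter* than 0.05 s terminates the chain by default (the
  minimum interval is read as a chain-validity/refractory bound;
  near-coincident discharges are one event, not train members);
  `shortGapBreaks = FALSE` tolerates them instead;
- "spiking time equal to 1 s" is read as a minimum train *span*
  (`minTrainDuration = 1`), the only reading we found consistent with
  its role in defining a train; it could conceivably be a merging
  window or a reporting bin, so it is exposed rather than hard-coded.

## Sleep staging

Four features per 10 s epoch contribute equally:

| feature | definition | anchors |
|---|---|---|
| delta ratio | epoch delta power / recording median | 0.5 (wake/paradoxical), 1 (SWS) |
| theta:delta | within-epoch ratio | 1.3 (wake/SWS), 3 (paradoxical) |
| EMG ratio | epoch 30–100 Hz EMG power / recording median | 1 (SWS/paradoxical), 2.4 (wake) |
| activity | epoch mean of the activity channel | 0.1 (active-wake override) |

"Maximum probability at ratio $x$" is realized as a piecewise-linear
membership ramping between the two printed anchors and saturating at
0/1 beyond them — the commercial scorer's internal curve is
proprietary, and ramps are the simplest shape consistent with the
printed anchor semantics. A stage's score is the unweighted mean of its
three memberships ("equal contribution" read as a mean; a product or a
hierarchical cascade would weight features unequally near saturation).
An epoch is active wake outright when activity exceeds 0.1 on its
native scale or the EMG ratio reaches 1.5 × the wake anchor (3.6);
otherwise the arg-max of wake/SWS/paradoxical wins, ties broken
wake > SWS > paradoxical (most- to least-common stage; declared, not
derived).

**Baselines.** The reference for the delta and EMG ratios is the
recording-wide *median* (configurable to mean), chosen for robustness
to seizure-like epochs. The median convention has an arithmetic
consequence worth stating plainly: whichever stage's power distribution
contains the recording median has ratios centred near 1 by
construction. On a majority-sleep multi-hour recording the median falls
in the lower tail of the SWS delta distribution, so SWS epochs sit at
ratios well above 1 and wake epochs well below 0.5 — but no generator
or recording can make "delta ratio ≥ 1" true for ~100 % of SWS epochs
while the median is defined over a session that is mostly SWS. The
classifier is robust to this because the other two features saturate;
end-to-end accuracy on 72 h synthetic sessions is ~99 % of epochs. For
*short* recordings (tens of minutes) whose realized stage mix strays
far from a sleep-majority composition, the median baseline is the wrong
reference and staging quality degrades; use multi-hour recordings or a
fixed baseline.

The EMG feature band is 30–100 Hz, inside the hardware low-pass; the
sleep epoch is 10 s (the band-averaging epoch); both configurable.

## HD-MEA network bursts

The two assays are modelled as data, not hardware: a 30 s full-chip
activity scan (per-electrode rate = count/duration, top-1024 selection
with ties to the lower electrode id) and a 300 s network scan.

The network-activity trace pools all spikes into 10 ms bins, converts
to spikes/s and convolves with a unit-area Gaussian kernel of SD
100 ms, truncated at ±4σ (direct convolution, zero-padded; the trace
integral reproduces the total spike count to < 0.01 %). Bin and kernel
widths are our declared defaults — nothing in the source material fixes
them — chosen to resolve sub-second inter-burst intervals while
smoothing single-electrode jitter.

**Burst detection.** Bursts are maximal excursions above
$\mathrm{median} + m \times 1.4826\,\mathrm{MAD}$. Robust statistics
are used because burst periods inflate a plain SD. The multiplier
defaults to $m = 7$: a 300 s smoothed Poisson background has a
correlation time of roughly two kernel SDs, i.e. thousands of
effectively independent trace samples, so a 3-SD threshold crosses on
noise alone several times per scan (we measured 3.7–5.8 robust SDs as
the typical *maximum* noise excursion across seeds), while synchronized
bursts sit tens of robust SDs above baseline. Seven separates the two
regimes with margin on both sides. Burst boundaries extend outward to
10 % of the peak height *above baseline* (trace median), clipped at
inter-peak minima; referencing the raw peak instead
(`boundaryRef = "absolute"`) makes every burst span its whole
inter-peak interval whenever the background exceeds 10 % of the peak,
as it does on a dense 1024-electrode raster. The IBI is the time
between successive burst peaks and is reported `NA` with fewer than two
bursts.

## Synthetic data: what it emulates, and what it does not

**EEG sessions.** Sleep states evolve as a first-order Markov chain at
10 s epoch granularity (no mid-epoch transitions — matching the
epoch-granular scorer and keeping ground truth exact). The default
transition matrix is the mixture form $T = s I + (1-s)\,\mathbf{1}\pi^T$
with stay probability $s = 0.85$ and stationary occupancy
$\pi = (0.10, 0.20, 0.55, 0.15)$ for active wake / wake / SWS /
paradoxical: geometric bouts of ~100 s and a sleep-majority mix typical
of a multi-day home-cage recording. Per epoch, the EEG is a sum of
band-limited Gaussian noise (complex-Gaussian Fourier coefficients
confined to each band) at stage-dependent RMS amplitudes, so PSD
estimates carry realistic chi-squared variance — a sinusoid generator
would validate nothing about estimator noise. Defaults (μV RMS):

| stage | delta | theta | alpha | beta | gamma | EMG | activity |
|---|---|---|---|---|---|---|---|
| active wake | 10 | 10 | 6 | 5 | 4 | 25 | 0.5 |
| wake | 10 | 10 | 6 | 5 | 4 | 14 | 0 |
| SWS | 45 | 10 | 6 | 5 | 4 | 10 | 0 |
| paradoxical | 7 | 25 | 6 | 5 | 4 | 6 | 0 |

These are calibrated once so the staging anchors are reachable under
the median baseline: SWS delta power ~20× wake so the median (low tail
of SWS) leaves wake ratios ≤ 0.1; wake EMG power lands between the wake
anchor (2.4) and the active-wake override (3.6) relative to the median;
paradoxical theta:delta ≈ 13 ≫ 3. A log-normal per-epoch amplitude
jitter (SD 0.1) adds biological variability beyond estimator noise.
Spike trains are planted as biphasic 350 μV, 8 ms templates (Poisson
train times, 4–8 spikes per train, onset gaps uniform on 0.1–0.4 s).

Not emulated: circadian structure, bout-length heavy tails, 1/f
broadband background, volume-conduction artifacts, movement artifacts
correlated with activity, or mid-epoch state transitions. Passing
recovery tests on this generator therefore demonstrates the *pipeline's
rules are implemented correctly and are mutually consistent*, not that
the thresholds are optimal for any particular animal preparation.

**MEA rasters.** Background firing is independent homogeneous Poisson
per electrode (1 Hz default). Burst peaks follow a renewal process
(exponential gaps at the configured bursts/min plus a refractory
minimum separation) with a 0.5 s edge margin so planted bursts are
whole. The refractory default is `max(1, 6 * burstSigma)`: the
*observable* envelope is the planted spike-time SD combined in
quadrature with the analysis kernel SD, so resolvability requires
separation in units of that combined width; cultures do not re-burst
faster than about once a second in any case. During a burst a random
60 % of electrodes add spikes under a Gaussian envelope (SD 100 ms) at
an extra intensity of (multiplier − 1) × the reference rate; the
reference is the background rate, or 1 Hz when the background is zero
so that a silent-background raster still contains its planted bursts.
Not emulated: electrode crosstalk, burst propagation (our bursts are
zero-lag synchronous), development over days in vitro, rate
heterogeneity across electrodes.

**Genotype effects.** `injectGenotypeEffect()` maps the heterozygote
onto the generators: delta amplitude × √2 (delta power doubled),
spike-train rate × 2, burst rate × 2, refractory interval × 0.5, SWS
occupancy × 0.85 (a transition-matrix tilt, skipped with a warning if a
custom matrix is supplied). Wild type is the identity. The magnitudes
reproduce the qualitative phenotype direction (delta up, spike trains
up, SWS down, bursts up, IBI down) at sizes detectable with 8–11
subjects per group.

## Statistics layer

Genotype comparisons use the pooled-variance two-tailed Student t-test
(group variances are similar by construction in the settings this
models; Welch is a flag). The two-way repeated-measures ANOVA is the
classical mixed decomposition — genotype between subjects, time within,
subject nested in genotype — fit with `aov` and an `Error(subject)`
stratum, requiring a complete design; per-time pooled t-tests are Sidak
adjusted, $p' = 1-(1-p)^m$ (Bonferroni and Holm selectable, as all
three appear in the reporting conventions this mirrors). An optional
"within two SD of the group mean" pre-filter exists but is off by
default: on clean Gaussian data it discards about 5 % of genuine
observations, so enabling it is an explicit user decision. Per-metric
group sizes are surfaced in every result because usable n commonly
varies by measure.

## Numerical and validation choices

- Degenerate inputs: constant epochs give all-zero spectra (not
  errors); zero epoch delta power maps theta:delta to a configured
  ceiling (100); a flat recording (zero median power) is a validation
  error; an all-artifact recording refuses to stage.
- Determinism: both simulators reseed from their config
  (`set.seed(cfg$seed)`), so identical configs give bit-identical
  output; the pipeline itself is deterministic.
- Validation problem sizes: the hypnogram-recovery experiment uses one
  full 72 h session (25,920 epochs; recovered within < 1 percentage
  point per stage); burst recovery uses 100 seeded rasters of 256
  electrodes × 300 s (exact count recovery, mean IBI error ≪ 1 bin);
  the effect-detection experiment uses 50 cohorts of 8 + 8 subjects
  with 120 s wake-locked sessions — stage locking removes stage-mix
  sampling variance from the between-subject contrast, which is the
  honest way to test the *statistics layer's* power at desk scale
  (unlocked multi-hour cohorts confound the delta contrast with
  occupancy sampling noise); null calibration uses 1000 replicates of
  the t-test on N(0,1) metrics.

## Known limitations

- The staging thresholds are fixed rule anchors, not fitted; no claim
  is made that they transfer to other species, electrode placements or
  filter settings.
- The median baseline requires multi-hour, sleep-majority recordings
  (see above).
- Burst detection assumes near-synchronous population bursts; slowly
  propagating or partial-network events will blur under the 100 ms
  kernel and may merge or fall under threshold.
- EDF output requires integer seconds and integer sampling rates; use
  the TSV format otherwise.
- The RM-ANOVA requires complete designs; subjects with missing cells
  must be dropped by the caller (the per-metric n report makes this
  visible).
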
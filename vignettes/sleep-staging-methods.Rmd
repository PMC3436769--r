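---
title: "Single-channel EOG sleep staging: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel EOG sleep staging: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eogstager)
```

## The staging problem and the signal model

Conventional sleep staging assigns one of five labels (W, N1, N2, N3,
REM) to each 30-s epoch of a polysomnogram, using central EEG, chin EMG
and two EOG channels. This package implements staging from a *single*
derived channel: the right-minus-left EOG difference. The physics behind
the derivation: the eyes are electrical dipoles, so conjugate eye
movements produce anti-phase potentials at the two peri-ocular
electrodes and *add* in the difference, while volume-conducted cerebral
activity that is common to both sites cancels — but not completely,
because the two electrodes do not see identical cortex. The difference
signal therefore carries eye movements at full strength plus attenuated
frontal EEG, which is enough to see slow waves (N3), spindle/sigma
activity (N2), the theta background of N1/REM, and the alpha + EMG
mixture of relaxed wake. High-frequency content of the difference also
reflects (peri-ocular) muscle tone, standing in for the chin EMG.

Assumptions this inherits: both EOG channels share one sampling rate and
amplitude calibration (µV); the montage is symmetric enough for the
cancellation argument; and muscle activity reaches the forehead/ocular
sites (true for wake tension and REM atonia, the two contrasts the tree
uses).

## Processing pipeline

1. **Read** the two channels from EDF, applying the header's
   digital-to-physical scaling (thresholds are amplitude-dependent, so
   physical units matter).
2. **Derive** REOG − LEOG (`deriveStagingSignal()`; `swap` covers
   mislabeled montages).
3. **Resample** to 256 Hz by linear interpolation when the recording is
   at 128 Hz. Only integer upsampling is supported; the final fractional
   sample holds the last value rather than extrapolating.
4. **High-pass** at 0.3 Hz (2nd-order Butterworth, forward-backward).
   Whether any pre-filtering should precede feature extraction is an
   open point; it is a config field (`highpassHz`, 0 disables) rather
   than a claim. The delta band starts at 0.75 Hz, so the default only
   removes electrode drift.
5. **Epoch** into 30-s blocks from sample 0 (a `startOffset` aligns to a
   manual hypnogram when needed); a trailing partial epoch is dropped
   and counted.

## Features

All spectral features come from one Welch estimate per epoch: 2-s
Hamming windows, 50% overlap, segments demeaned — 0.5 Hz resolution, 29
averages per 30-s epoch, the standard compromise between variance and
resolution at this epoch length. Band powers integrate the one-sided
density over delta 0.75–4, theta 4–8, alpha 8–12, sigma 12–16, beta
16–32 and EMG 32–64 Hz (bands are config fields; the EMG band may be
32–128 Hz where the recording supports it). Ratios:

| Feature | Definition | Reads as |
|---|---|---|
| SBI | sigma / beta | spindle-band dominance (N2 high, REM low) |
| DBI | delta / beta | slow-wave dominance (N3 ≫ N2 > W) |
| BEI | beta / EMG | cortical fast activity vs muscle tone |
| EMI | delta raw / delta median-filtered | sharp transients / movement artifact |

Division is guarded by `max(denominator, 1e-12)`; a ratio whose
numerator and denominator are both below the guard reports 0, so an
all-zero epoch yields all-zero features rather than NaN. Scaling an
epoch by c > 0 scales every band power by c² and leaves all four ratios
unchanged (a tested invariant). The EMI median filter is 0.25 s (65
samples at 256 Hz): long enough to delete spikes and blinks' sharp
edges, short enough to pass genuine slow waves, so EMI ≈ 1 in clean
sleep and grows with transient contamination.

Event detectors (all rule-based, all config-driven):

* **Spindles** — sigma-band (2nd-order Butterworth) envelope as a 0.25-s
  sliding RMS; events are maximal runs above `spindle_threshold_k` (3×)
  the *record-wide* median envelope, with duration inside
  [`spindle_min_dur`, `spindle_max_dur`] = [0.5, 2] s.
* **Arousals** — alpha+beta (8–32 Hz) power in 1-s windows stepped by
  0.5 s must rise ≥ `arousal_threshold_k` (2.5×) over the median of the
  trailing 60 s, with a concurrent 1.5× EMG rise, sustained 3–15 s.
  Events are attributed to the epoch containing their onset (NAR); LAR
  is the arousal seconds overlapping each epoch, capped at 30.
* **Eye movements** — on the 6 Hz low-passed signal, runs with
  |amplitude| ≥ `em_amplitude` (75 µV) for ≥ 0.1 s, classified rapid vs
  slow at a peak slope of `em_slope_cutoff` (100 µV/s). Rapid events are
  REM saccades; slow ones are blinks and the slow rolling eye movements
  of drowsiness.

A numerical subtlety in both windowed detectors: a sliding window smears
an event's above-threshold run by roughly one window length, so duration
rules are applied to the smear-corrected duration (run length minus one
window). Without the correction a 0.2-s sigma burst passes the 0.5-s
spindle floor and a 2-s power shift passes the 3-s arousal floor, which
is exactly what the rules exist to prevent.

## The decision tree

Branches are evaluated in a fixed order and the first satisfied one
wins; there are no scores and no tie-breaking beyond order. N1 — the
stage human scorers agree on least — is deliberately the fall-through
leaf rather than a positively detected class.

1. **W.emg**: EMG power ≥ `wake_emg_power` ∧ BEI ≥ `wake_bei`
2. **W.alpha**: alpha fraction of summed EEG band power ≥ `wake_alpha_fraction`
3. **W.ocular**: slow eye movements ≥ `wake_slow_em_count`
4. **W.artifact**: EMI ≥ `wake_emi`
5. **W.arousal**: arousals in the trailing 3 epochs ≥ `wake_nar_floor`
6. **N3**: DBI ≥ `n3_dbi` ∧ delta fraction ≥ `n3_delta_fraction` ∧ EMG ≤ `n3_emg_ceiling`
7. **R**: EMG ≤ `rem_emg_ceiling` ∧ rapid EMs ≥ `rem_rapid_em_count` ∧
   SBI ≤ `rem_sbi_ceiling` ∧ DBI ≤ `rem_dbi_ceiling` ∧ NSP = 0
8. **N2.spindle**: NSP ≥ `n2_nsp_floor`; **N2.sigma**: SBI ≥ `n2_sbi`
9. **N1**: fall-through

Each decision records its fired branch, so misclassification can be
traced to a rule. Staging is deterministic, bit-for-bit, for fixed input
and configuration. An optional 3-epoch majority smoother (off by
default; three-way ties keep the original label) cleans isolated flips.
Whether the tree should consult neighbouring epochs for REM continuity
is left open; the default is single-epoch, with the trailing arousal
window as the only sequence context.

### The 23 thresholds and their calibration

`thresholdNames()` enumerates the 23 tunable scalars. The deployed
values of the original instrument are proprietary and unpublished, so
the shipped defaults are this package's own calibration: a grid search
maximizing epoch accuracy on a fixed-seed high-contrast synthetic
training record (seed 7041), refined once when the REM DBI ceiling
was found to clip eye-movement-inflated REM epochs (rapid deflections
add low-frequency power, so REM epochs legitimately reach DBI ≈ 20; the
ceiling is 25 and N2/N3 are excluded from the REM branch by the atonia
ceiling and the rapid-EM requirement, not by DBI). The calibration was
fixed before the acceptance runs and is not a claim about the original
instrument's values.

When the effective EMG band is 32–64 Hz instead of 32–128 Hz, roughly
two thirds of a white-ish EMG spectrum is lost, so `adaptThresholds()`
divides the EMG power threshold by 3 and multiplies the BEI threshold by
3, leaving the other 21 values bit-identical; the mapping is idempotent
per band and exactly invertible. "Reduced by two thirds" admits a
second reading (×2/3, with BEI ×3/2); both are implemented
(`reduction = "two-thirds"`), the ×1/3 reading is the default.

## The synthetic generator

The generator exists so that every module — EDF I/O, resampling,
features, tree, agreement — is testable end-to-end with known truth.
It emulates, per stage: band-limited Gaussian noise with stage-specific
RMS amplitudes in the five EEG bands and the EMG band; spindle bursts
(13 Hz under a Hann envelope, 0.7–1.3 s) in N2; dominant slow-wave
amplitude in N3; ±150 µV rapid deflections in REM; 150 µV slow blink
deflections in W; and an in-phase shared cerebral component that cancels
in the difference while the informative components are split anti-phase.
Truth hypnograms come from an epoch-scale Markov chain whose transition
matrix is built from an SDB severity profile: stationary distribution
equal to the profile's stage fractions *exactly* (a reversible
symmetric-flow construction), mean bout lengths near a default table
(W 4, N1 2, N2 12, N3 8, REM 16 epochs — realized bouts run slightly
long, the price of exact stationarity). A Markov chain rather than a
semi-Markov bout model keeps stationarity controllable; it does not
reproduce the ultradian NREM/REM cycle. Respiratory events are a
homogeneous Poisson process over sleep epochs at the profile's RDI
(6/15/31/71 events per hour for normal/mild/moderate/severe), and a
profile-scaled random subset of events triggers a 5-s alpha+EMG arousal
burst, qualitatively reproducing the wake/N1 confusion that grows with
SDB severity.

The severity profiles' stage fractions use the pooled validation
cross-tabulations; for the moderate/severe group the printed "% epochs"
row is inconsistent with its own row counts (it sums to 73.7%, evidently
divided by the other group's total), so the fractions are derived from
the row epoch counts instead.

The `contrast` dial interpolates all stage-specific amplitudes toward
their across-stage mean and scales event rates; at 0 every epoch is
statistically identical and the tree (correctly) emits the fall-through
stage for essentially everything, so recovery of W/N2/N3/R collapses to
~0 while N1 "recovery" is trivially high — a useful negative control for
any fall-through classifier. What passing tests on this generator shows:
the pipeline recovers stages whose spectral/event signatures are
present and separated. What it does not show: performance on real
recordings, whose stage signatures overlap far more (transitional
epochs, K-complexes, artifacts, inter-subject amplitude variability are
all absent from the generator).

## Agreement statistics

* **Per-stage kappa** collapses the 5×5 table one-vs-rest and applies
  Cohen's formula to the 2×2; this variant reproduces all ten published
  pooled kappas from the printed margins (verified against an
  independent brute-force implementation to 10⁻¹²; κ = 0 is returned
  when chance agreement is 1). The published tables ship in
  `publishedAgreementTables()`; `reconstructCounts()` inverts row
  percentages × row totals to integers, correcting each row's rounding
  residual into its largest cell (the permissible residual scales with
  how far the printed row sum is from 100%, since a row printed as
  99.9% of 18,167 epochs legitimately leaves ~18 epochs unplaced).
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures — is used for per-subject staged minutes. The published ICC
  table does not state its variant and per-subject minutes are
  unpublished, so the choice cannot be verified against print; ICC(2,1)
  is the conservative default (a constant offset between scorers lowers
  it, unlike Pearson correlation).
* **Bland-Altman** limits use bias ± exactly 2·SD (the convention of the
  validation literature, not 1.96), differences oriented automated −
  manual.
* **Sleep onset** is the first epoch of the earliest run of ≥ 3
  consecutive non-wake epochs, returned 1-based (R convention); onset
  *differences* in minutes are binned (−∞,3], (3,10], (10,20], (20,∞) —
  with 30-s epochs the printed labels "≤3 / 4–10 / 11–20 / >20 min"
  map exactly onto these half-open intervals.
* **TST/SE/RDI**: TST = 0.5 min × non-wake epochs; SE = 100·TST /
  recording time (recording time is an explicit input — lights-on/off
  trimming is out of scope); RDI = events / hours of sleep, flagged
  undefined at TST = 0. Per-subject sensitivity/PPV use a 20-epoch
  manual-positive inclusion floor, reported as an exclusion flag rather
  than an error.

## Degenerate inputs and numerical policy

All-zero records stage to N1 through the guard rules; empty confusion
tables, < 3 ICC pairs, < 2 Bland-Altman pairs, zero-variance rater pairs
and TST = 0 raise errors or flags as documented rather than NaN.
Rounding (kappa to 2 decimals, percentages to 1) is display-only in
`renderReport()`; tests and internal comparisons use full precision.
EDF round-trips are exact up to one 16-bit quantization step of the
written physical range (a fixture-writer property, not a float-precision
identity).

## Problem sizes used by the test and acceptance runs

Unit fixtures are seconds to minutes of signal; the end-to-end staging
and severity checks use 960-epoch (8-h) nights at 128 Hz, the size of a
clinical recording, one seeded night per condition. The whole suite and
the acceptance script each complete in a few minutes on one core.

## Known limitations

Thresholds are synthetic-calibrated (see above); N1 has no positive
detector by design, so N1 sensitivity is structurally poor — consistent
with human inter-rater behaviour on N1, but a limitation nonetheless;
K-complexes, cyclic alternating pattern, ECG/movement artifact channels
and spectral estimators beyond Welch are out of scope; EDF+ annotations
are not parsed; statistical inference on kappa/ICC (CIs, p-values) is
not provided.
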
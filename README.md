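# eogstager

Automated five-stage sleep staging (W / N1 / N2 / N3 / REM) from a single
differential electrooculogram (EOG) channel, with the full
manual-versus-automated agreement toolkit used to validate such
algorithms, and a synthetic polysomnography (PSG) generator so the whole
system can be exercised and tested without any recorded data.

## Who this is for

Sleep researchers and engineers who want to

* stage overnight recordings from self-applied forehead/EOG sensors when a
  full PSG montage (central EEG, chin EMG) is not available,
* quantify epoch-by-epoch agreement between two scorers (human or
  algorithmic) the way validation studies report it — confusion tables,
  per-stage Cohen's kappa, sensitivity/PPV, intraclass correlation,
  Bland-Altman limits, sleep-onset differences — or
* simulate PSG-like two-channel EOG data with controlled sleep
  architecture and sleep-disordered-breathing (SDB) severity.

## The method

The staging input is the difference signal REOG − LEOG: conjugate eye
movements are anti-phase across the two peri-ocular electrodes and add in
the difference, while it also retains residual frontal EEG. Recordings at
128 Hz are upsampled to 256 Hz by linear interpolation. For every 30-s
epoch the package computes, by Welch's method (2-s Hamming windows, 50%
overlap):

* band powers in delta (0.75–4 Hz), theta (4–8), alpha (8–12), sigma
  (12–16), beta (16–32) and an EMG band (32–64 or 32–128 Hz);
* the ratio features
  **SBI** = sigma/beta, **DBI** = delta/beta, **BEI** = beta/EMG, and
  **EMI** = delta power before / after a 0.25-s median filter (a
  transient/artifact index);
* event counts: sleep spindles (**NSP**, sigma-envelope threshold with a
  0.5–2 s duration rule), arousals (**NAR/LAR**, alpha+beta power shift
  over a trailing baseline with concurrent EMG rise, 3–15 s), and rapid
  vs. slow eye movements (amplitude threshold, classified by peak slope).

A hierarchical decision tree then assigns each epoch the first satisfied
label: Wake (high EMG ∧ high BEI, or alpha dominance, or ocular/artifact/
arousal evidence) → N3 (high DBI ∧ high delta fraction ∧ low EMG) → REM
(EMG atonia ∧ rapid eye movements ∧ low SBI, no spindles) → N2 (spindles
or high SBI) → N1 (fall-through). The tree is governed by exactly 23
named thresholds in a YAML-round-trippable `StagerConfig`. When the
effective EMG band is halved to 32–64 Hz, the EMG power threshold is
divided by 3 and the BEI threshold multiplied by 3; the other 21
thresholds are untouched (`adaptThresholds()`).

Agreement between a manual and an automated hypnogram is summarized as in
the validation literature: 5×5 confusion table, per-stage one-vs-rest
Cohen's kappa κ = (P₀ − Pₑ)/(1 − Pₑ), row-percentage agreement,
per-subject sensitivity/PPV (with a 20-epoch inclusion floor), ICC(2,1)
of per-subject staged minutes, Bland-Altman bias ± 2·SD for TST, sleep
efficiency and RDI, and sleep onset defined as the first run of three
consecutive non-wake epochs, with onset differences binned at 3/10/20
minutes. `reconstructCounts()` inverts published percentage tables back
to integer counts so printed results can be re-analyzed.

## Worked example

Reconstruct a published pooled cross-tabulation (row percentages + row
epoch totals) and recompute the per-stage kappas:

```r
library(eogstager)
pub <- publishedAgreementTables()$normalMild
tab <- reconstructCounts(pub$rowPercent, pub$rowTotals)
round(perStageKappa(tab), 2)
#>    W   N1   N2   N3    R
#> 0.67 0.21 0.60 0.76 0.72
```

The kappas match the printed values; N1 is by far the least reliable
stage, as expected — it is the waste-basket between wake and light sleep.

Simulate a synthetic night, stage it end-to-end and score the agreement
against the known truth:

```r
dir <- tempfile()
fx  <- writeFixture(dir, sdbProfile("mild"), synthesisParams(1),
                    nEpochs = 120, seed = 42)
res <- stagePsg(fx$edf)              # EDF -> difference -> 256 Hz -> tree
res$hypnogram
#> Hypnogram: 120 epochs of 30 s
#>    W:23  N1:10  N2:33  N3:48  R:6
confusionMatrix(fx$hypnogram, res$hypnogram)  # diagonal: all 120 recovered
s <- sleepSummary(res$hypnogram,
                  events = readRespiratoryEvents(fx$eventsCsv))
str(s[c("tstMinutes", "sleepEfficiency", "rdi")])
#> $ tstMinutes     : num 48.5
#> $ sleepEfficiency: num 80.8
#> $ rdi            : num 13.6
```

TST is half a minute per non-wake epoch (97 × 0.5 = 48.5 min), sleep
efficiency is TST over recording time, and the RDI divides the simulated
respiratory events by hours of sleep.

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/eogstager.R simulate --out night/ --profile severe --epochs 960 --seed 7
Rscript inst/cli/eogstager.R stage --edf night/psg.edf --left-eog LEOG \
        --right-eog REOG --out auto.csv
Rscript inst/cli/eogstager.R agree --manual night/hypnogram.csv --auto auto.csv \
        --report report.json
```

## Limitations

The shipped 23 threshold defaults are calibrated on this package's
synthetic generator, not on clinical recordings; real-data use requires
re-tuning via the YAML config (`writeStagerConfig()`), and the vignette
discusses what the synthetic data do and do not emulate. Respiratory
events are taken as given (event detection from airflow/SpO₂ is out of
scope), and EDF support covers continuous two-channel reads plus a
fixture-grade writer, not EDF+ annotations.
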
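Package: eogstager
Title: Automated Sleep Staging from a Differential Electrooculogram Channel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-stage (W/N1/N2/N3/REM) automated sleep staging from a single
    differential EOG or forehead-EEG channel. Computes per-epoch spectral band
    powers (delta, theta, alpha, sigma, beta, EMG), the SBI/DBI/BEI/EMI power
    ratios, and spindle, arousal and eye-movement event counts, and classifies
    each 30-second epoch with a configurable hierarchical decision tree,
    including the threshold adaptation for a reduced 32-64 Hz EMG band.
    Includes EDF signal input, a synthetic polysomnography generator with
    sleep-disordered-breathing severity profiles for end-to-end testing, and a
    manual-versus-automated agreement suite: confusion tables, per-stage
    Cohen's kappa, sensitivity/PPV, intraclass correlation, Bland-Altman
    limits, sleep-onset detection and TST/sleep-efficiency/RDI summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agreement.R'
    'cli-report.R'
    'features.R'
    'signal-io.R'
    'stager.R'
    'synthetic.R'
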
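#' @import methods
NULL

#' Canonical sleep stage labels
#'
#' Stage order used throughout the package: Wake, N1, N2, N3 (slow-wave
#' sleep) and REM, in that order. Confusion tables, kappa vectors and
#' transition matrices all follow this ordering.
#'
#' @export
STAGES <- c("W", "N1", "N2", "N3", "R")

## ---------------------------------------------------------------------------
## RawChannel

#' RawChannel: a single fixed-rate physiological signal
#'
#' Holds one channel of uniformly sampled data in physical units
#' (microvolts for EOG/EEG/EMG).
#'
#' @slot label channel label, e.g. "LEOG".
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot samples numeric vector of samples in physical units.
#' @slot physicalUnit unit string, "uV" expected for EOG.
#'
#' @export
setClass("RawChannel",
  representation(
    label = "character",
    samplingRate = "numeric",
    samples = "numeric",
    physicalUnit = "character"
  ),
  prototype(physicalUnit = "uV")
)

setValidity("RawChannel", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@samples) < 1)
    msg <- c(msg, "channel must contain at least one sample")
  if (length(object@label) != 1)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RawChannel
#'
#' @param samples numeric vector of samples (physical units).
#' @param samplingRate sampling rate in Hz.
#' @param label channel label.
#' @param physicalUnit unit string (default "uV").
#' @return a [RawChannel-class] object.
#' @examples
#' ch <- rawChannel(sin(2 * pi * 10 * seq(0, 1, by = 1/128)), 128, "LEOG")
#' samplingRate(ch)
#' @export
rawChannel <- function(samples, samplingRate, label = "signal",
                       physicalUnit = "uV") {
  new("RawChannel", label = label, samplingRate = as.numeric(samplingRate),
      samples = as.numeric(samples), physicalUnit = physicalUnit)
}

## ---------------------------------------------------------------------------
## EpochedSignal

#' EpochedSignal: a signal segmented into fixed-length scoring epochs
#'
#' Samples are stored as an nSamplesPerEpoch x nEpochs matrix; a trailing
#' partial epoch is dropped at construction and its sample count recorded.
#'
#' @slot samplingRate sampling rate in Hz.
#' @slot epochLength epoch length in seconds (30 by convention).
#' @slot epochs numeric matrix, one column per epoch.
#' @slot droppedSamples number of trailing samples discarded.
#' @slot label label of the source channel.
#'
#' @export
setClass("EpochedSignal",
  representation(
    samplingRate = "numeric",
    epochLength = "numeric",
    epochs = "matrix",
    droppedSamples = "integer",
    label = "character"
  )
)

setValidity("EpochedSignal", function(object) {
  msg <- character()
  blk <- object@epochLength * object@samplingRate
  if (abs(blk - round(blk)) > 1e-9)
    msg <- c(msg, "epochLength x samplingRate must be an integer sample count")
  if (nrow(object@epochs) != round(blk))
    msg <- c(msg, "each epoch must have exactly epochLength x samplingRate samples")
  if (ncol(object@epochs) < 1)
    msg <- c(msg, "at least one full epoch required")
  if (object@droppedSamples < 0)
    msg <- c(msg, "droppedSamples must be nonnegative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Hypnogram

#' Hypnogram: per-epoch sleep-stage labels
#'
#' @slot stages character vector of labels drawn from [STAGES].
#' @slot epochLength epoch length in seconds.
#' @slot startTime optional start timestamp (POSIXct of length 0 or 1).
#'
#' @export
setClass("Hypnogram",
  representation(
    stages = "character",
    epochLength = "numeric",
    startTime = "POSIXct"
  ),
  prototype(epochLength = 30, startTime = as.POSIXct(character()))
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@stages) < 1)
    msg <- c(msg, "hypnogram must contain at least one epoch")
  bad <- setdiff(unique(object@stages), STAGES)
  if (length(bad))
    msg <- c(msg, paste0("invalid stage label(s): ", paste(bad, collapse = ", ")))
  if (length(object@epochLength) != 1 || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector of stage labels (subset of [STAGES]).
#' @param epochLength epoch length in seconds (default 30).
#' @param startTime optional POSIXct start time.
#' @return a [Hypnogram-class] object.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2", "N3"))
#' nEpochs(h)
#' @export
hypnogram <- function(stages, epochLength = 30, startTime = NULL) {
  if (is.null(startTime)) startTime <- as.POSIXct(character())
  new("Hypnogram", stages = as.character(stages),
      epochLength = as.numeric(epochLength), startTime = startTime)
}

## ---------------------------------------------------------------------------
## StagerConfig

#' StagerConfig: band scheme plus the 23 decision-tree thresholds
#'
#' The classifier is governed by exactly 23 named scalar thresholds (listed
#' in [thresholdNames()]), the spectral band scheme, the effective EMG band
#' and a smoothing flag. Configurations round-trip through YAML unchanged
#' via [readStagerConfig()] / [writeStagerConfig()].
#'
#' @slot bands named list of c(lo, hi) Hz intervals for delta, theta, alpha,
#'   sigma and beta.
#' @slot emgBand c(lo, hi) Hz interval of the effective EMG band
#'   (32-64 or 32-128).
#' @slot thresholds named numeric vector of the 23 decision thresholds.
#' @slot smoothing logical; apply the optional 3-epoch majority filter.
#' @slot highpassHz high-pass corner applied before feature extraction
#'   (0 disables).
#'
#' @export
setClass("StagerConfig",
  representation(
    bands = "list",
    emgBand = "numeric",
    thresholds = "numeric",
    smoothing = "logical",
    highpassHz = "numeric"
  )
)

#' Names of the 23 tunable decision thresholds
#'
#' @return character vector of length 23.
#' @export
thresholdNames <- function() c(
  "wake_emg_power",      # uV^2, EMG power above which W.emg can fire (EMG-band adapted)
  "wake_bei",            # beta/EMG ratio floor for W.emg (EMG-band adapted)
  "wake_alpha_fraction", # alpha share of summed EEG band power for W.alpha
  "wake_slow_em_count",  # slow eye-movement (blink/SEM) count floor for W.ocular
  "wake_emi",            # EMI (transient/artifact index) floor for W.artifact
  "wake_nar_floor",      # trailing 3-epoch arousal count floor for W.arousal
  "n3_dbi",              # delta/beta ratio floor
  "n3_delta_fraction",   # delta share of summed EEG band power floor
  "n3_emg_ceiling",      # uV^2 EMG power ceiling for N3
  "rem_emg_ceiling",     # uV^2 EMG power ceiling (atonia) for REM
  "rem_rapid_em_count",  # rapid eye-movement count floor for REM
  "rem_sbi_ceiling",     # sigma/beta ceiling for REM
  "rem_dbi_ceiling",     # delta/beta ceiling for REM
  "n2_nsp_floor",        # spindle count floor for N2
  "n2_sbi",              # sigma/beta floor for spindle-free N2
  "spindle_threshold_k", # sigma envelope threshold, multiples of record median
  "spindle_min_dur",     # s
  "spindle_max_dur",     # s
  "arousal_threshold_k", # alpha+beta power rise over trailing baseline
  "arousal_min_dur",     # s
  "arousal_max_dur",     # s
  "em_amplitude",        # uV deflection floor for eye-movement events
  "em_slope_cutoff"      # uV/s peak-slope boundary between rapid and slow
)

setValidity("StagerConfig", function(object) {
  msg <- character()
  need <- c("delta", "theta", "alpha", "sigma", "beta")
  if (!all(need %in% names(object@bands)))
    msg <- c(msg, paste("bands must name:", paste(need, collapse = ", ")))
  for (b in intersect(need, names(object@bands))) {
    iv <- object@bands[[b]]
    if (length(iv) != 2 || iv[1] < 0 || iv[2] <= iv[1])
      msg <- c(msg, paste0("band '", b, "' must be a positive-width interval"))
  }
  if (length(object@emgBand) != 2 || object@emgBand[2] <= object@emgBand[1])
    msg <- c(msg, "emgBand must be a (lo, hi) interval")
  tn <- thresholdNames()
  if (length(object@thresholds) != 23 ||
      !identical(sort(names(object@thresholds)), sort(tn)))
    msg <- c(msg, "thresholds must be exactly the 23 named values of thresholdNames()")
  else if (any(!is.finite(object@thresholds)) || any(object@thresholds < 0))
    msg <- c(msg, "thresholds must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-generator classes

#' HypnogramModel: Markov-chain model of stage succession
#'
#' @slot transition 5x5 row-stochastic matrix in [STAGES] order.
#' @slot initial initial stage distribution (length 5, sums to 1).
#' @slot nEpochs number of epochs to simulate.
#'
#' @export
setClass("HypnogramModel",
  representation(
    transition = "matrix",
    initial = "numeric",
    nEpochs = "integer"
  )
)

setValidity("HypnogramModel", function(object) {
  msg <- character()
  P <- object@transition
  if (!all(dim(P) == c(5, 5)))
    msg <- c(msg, "transition must be 5x5")
  else {
    if (any(P < -1e-12)) msg <- c(msg, "transition entries must be nonnegative")
    if (any(abs(rowSums(P) - 1) > 1e-9))
      msg <- c(msg, "transition rows must sum to 1 within 1e-9")
  }
  if (length(object@initial) != 5 || abs(sum(object@initial) - 1) > 1e-9 ||
      any(object@initial < -1e-12))
    msg <- c(msg, "initial must be a length-5 distribution")
  if (object@nEpochs < 1L)
    msg <- c(msg, "nEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a HypnogramModel
#'
#' @param transition 5x5 row-stochastic matrix ([STAGES] order).
#' @param initial initial stage distribution; default the uniform distribution.
#' @param nEpochs number of epochs.
#' @return a [HypnogramModel-class] object.
#' @export
hypnogramModel <- function(transition, initial = rep(1/5, 5), nEpochs = 960) {
  dimnames(transition) <- list(STAGES, STAGES)
  new("HypnogramModel", transition = transition, initial = as.numeric(initial),
      nEpochs = as.integer(nEpochs))
}

#' SdbProfile: sleep-disordered-breathing severity profile
#'
#' Bundles the target respiratory disturbance index, the target stage
#' distribution and an arousal-rate multiplier for one severity class.
#'
#' @slot severity one of "normal", "mild", "moderate", "severe".
#' @slot targetRdi respiratory events per hour of sleep.
#' @slot stageFractions length-5 stage distribution ([STAGES] order).
#' @slot arousalMultiplier scales the fraction of respiratory events that
#'   trigger a cortical arousal burst.
#'
#' @export
setClass("SdbProfile",
  representation(
    severity = "character",
    targetRdi = "numeric",
    stageFractions = "numeric",
    arousalMultiplier = "numeric"
  )
)

setValidity("SdbProfile", function(object) {
  msg <- character()
  if (!object@severity %in% c("normal", "mild", "moderate", "severe"))
    msg <- c(msg, "severity must be normal/mild/moderate/severe")
  if (object@targetRdi < 0) msg <- c(msg, "targetRdi must be >= 0")
  f <- object@stageFractions
  if (length(f) != 5 || any(f < 0) || abs(sum(f) - 1) > 1e-6)
    msg <- c(msg, "stageFractions must be a length-5 distribution (sum 1 within 1e-6)")
  if (length(msg)) msg else TRUE
})

#' SynthesisParams: stage-dependent signal-synthesis parameters
#'
#' Amplitudes are RMS microvolts of the *difference* (REOG-LEOG) signal per
#' spectral band and stage; event rates are expected events per 30-s epoch.
#'
#' @slot bandAmp 5x5 matrix, rows = stages ([STAGES]), columns = bands
#'   (delta, theta, alpha, sigma, beta), RMS uV.
#' @slot emgAmp per-stage EMG-band RMS uV (length 5).
#' @slot spindleRate expected spindles per N2 epoch.
#' @slot spindleAmp spindle peak amplitude, uV.
#' @slot remRate expected rapid eye movements per REM epoch.
#' @slot remAmp rapid eye-movement deflection amplitude, uV.
#' @slot blinkRate expected blinks/slow eye movements per W epoch.
#' @slot blinkAmp blink deflection amplitude, uV.
#' @slot sharedAmp RMS uV of the in-phase cerebral component common to both
#'   channels (cancels in the difference).
#' @slot noiseFloor per-channel sensor noise RMS uV.
#' @slot sampleRate output sampling rate, Hz.
#'
#' @export
setClass("SynthesisParams",
  representation(
    bandAmp = "matrix",
    emgAmp = "numeric",
    spindleRate = "numeric",
    spindleAmp = "numeric",
    remRate = "numeric",
    remAmp = "numeric",
    blinkRate = "numeric",
    blinkAmp = "numeric",
    sharedAmp = "numeric",
    noiseFloor = "numeric",
    sampleRate = "numeric"
  )
)

setValidity("SynthesisParams", function(object) {
  msg <- character()
  if (!all(dim(object@bandAmp) == c(5, 5)))
    msg <- c(msg, "bandAmp must be 5 stages x 5 bands")
  if (any(object@bandAmp < 0) || any(object@emgAmp < 0))
    msg <- c(msg, "amplitudes must be >= 0")
  if (length(object@emgAmp) != 5)
    msg <- c(msg, "emgAmp must have one entry per stage")
  rates <- c(object@spindleRate, object@remRate, object@blinkRate)
  if (any(rates < 0)) msg <- c(msg, "event rates must be >= 0")
  if (!object@sampleRate %in% c(128, 256))
    msg <- c(msg, "sampleRate must be 128 or 256 Hz")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AgreementReport

#' AgreementReport: epoch-by-epoch manual-vs-automated agreement
#'
#' @slot confusion 5x5 integer matrix, rows = manual stage, columns =
#'   automated stage ([STAGES] order).
#' @slot kappa per-stage one-vs-rest Cohen's kappa (length 5).
#' @slot rowPercent 5x5 row-percentage matrix.
#' @slot overallPercent overall percent agreement (trace / total x 100).
#' @slot sensitivity per-stage sensitivity, percent.
#' @slot ppv per-stage positive predictive value, percent.
#'
#' @export
setClass("AgreementReport",
  representation(
    confusion = "matrix",
    kappa = "numeric",
    rowPercent = "matrix",
    overallPercent = "numeric",
    sensitivity = "numeric",
    ppv = "numeric"
  )
)
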
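## Per-epoch spectral features and event detectors feeding the decision tree.

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hamming-windowed, 50%-overlapping
#' segments (2-s segments by default, giving 0.5 Hz resolution on a 30-s
#' epoch). Each segment is demeaned before windowing. The one-sided density
#' integrates to the signal variance (Parseval), so band powers obtained by
#' integrating it are in squared physical units.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param windowSec segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welchPsd <- function(x, fs, windowSec = 2, overlap = 0.5) {
  nper <- round(windowSec * fs)
  n <- length(x)
  if (n < nper) stop("welchPsd: signal shorter than one window")
  step <- max(1, floor(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- signal::hamming(nper)
  seg <- vapply(starts, function(s) x[s:(s + nper - 1)], numeric(nper))
  seg <- seg - rep(colMeans(seg), each = nper)
  seg <- seg * w
  X <- stats::mvfft(seg)
  half <- nper %/% 2 + 1
  p <- Mod(X[seq_len(half), , drop = FALSE])^2
  psd <- rowMeans(p) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nper is even)
  scale2 <- rep(2, half); scale2[1] <- 1
  if (nper %% 2 == 0) scale2[half] <- 1
  list(freq = (seq_len(half) - 1) * fs / nper, psd = psd * scale2)
}

#' Integrate a PSD over named frequency bands
#'
#' @param x numeric epoch samples.
#' @param fs sampling rate, Hz.
#' @param bands named list of c(lo, hi) intervals in Hz; bins with
#'   lo <= f < hi are summed.
#' @param windowSec Welch segment length, seconds.
#' @return named numeric vector of band powers (squared signal units).
#' @export
bandPowers <- function(x, fs, bands, windowSec = 2) {
  hi <- vapply(bands, `[`, numeric(1), 2)
  if (any(hi > fs / 2 + 1e-9))
    stop("bandPowers: band edge above Nyquist (", fs / 2, " Hz)")
  sp <- welchPsd(x, fs, windowSec = windowSec)
  df <- sp$freq[2] - sp$freq[1]
  vapply(bands, function(iv) {
    sum(sp$psd[sp$freq >= iv[1] & sp$freq < iv[2]]) * df
  }, numeric(1))
}

guardedRatio <- function(num, den, eps = 1e-12) {
  ifelse(num < eps & den < eps, 0, num / pmax(den, eps))
}

#' Ratio features SBI, DBI, BEI and EMI
#'
#' SBI = sigma/beta, DBI = delta/beta, BEI = beta/EMG band power ratios;
#' EMI = delta power of the raw epoch over the delta power of the
#' median-filtered epoch, an index of sharp transients and movement
#' artifact (median filtering preserves genuine slow waves, so EMI stays
#' near 1 in clean sleep). Denominators are guarded by
#' max(denominator, 1e-12), and a ratio with both terms below the guard
#' is reported as 0.
#'
#' @param bandPower named band powers including `delta`, `sigma`, `beta`.
#' @param emgPower EMG-band power.
#' @param deltaFiltered delta power of the median-filtered epoch (for EMI);
#'   NA omits EMI.
#' @return named numeric vector `c(sbi, dbi, bei, emi)`.
#' @export
computeRatios <- function(bandPower, emgPower, deltaFiltered = NA_real_) {
  c(sbi = guardedRatio(bandPower[["sigma"]], bandPower[["beta"]]),
    dbi = guardedRatio(bandPower[["delta"]], bandPower[["beta"]]),
    bei = guardedRatio(bandPower[["beta"]], emgPower),
    emi = if (is.na(deltaFiltered)) NA_real_ else
      guardedRatio(bandPower[["delta"]], deltaFiltered))
}

## ---------------------------------------------------------------------------
## filters and envelopes (internal)

butterFilt <- function(x, fs, lo = NULL, hi = NULL, order = 2) {
  nyq <- fs / 2
  if (!is.null(lo) && !is.null(hi)) {
    hi <- min(hi, nyq * 0.999)
    bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  } else if (!is.null(lo)) {
    bf <- signal::butter(order, lo / nyq, type = "high")
  } else {
    bf <- signal::butter(order, min(hi, nyq * 0.999) / nyq, type = "low")
  }
  as.numeric(signal::filtfilt(bf, x))
}

slidingRms <- function(x, k) {
  # centered sliding RMS over k samples
  cs <- c(0, cumsum(x^2))
  n <- length(x)
  half <- k %/% 2
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1] - cs[lo + 1]) / (hi - lo))
}

runsAboveThreshold <- function(mask, fs, minDur, maxDur = Inf) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(minDur * fs) &
    r$lengths <= round(maxDur * fs)
  data.frame(start = (starts[keep] - 1) / fs, end = ends[keep] / fs)
}

## ---------------------------------------------------------------------------
## event detectors

#' Detect sleep spindles
#'
#' A spindle is a maximal interval where the sigma-band (12-16 Hz) envelope
#' (0.25-s sliding RMS) exceeds `threshold` for a duration within the
#' configured bounds. When `threshold` is NULL it is taken as
#' `spindle_threshold_k` times the median envelope of `x` itself; over a
#' whole record the caller should pass the record-wide threshold so epochs
#' share one reference (as [extractFeatures()] does).
#'
#' @param x numeric samples (one epoch or a whole record).
#' @param fs sampling rate, Hz.
#' @param config a [StagerConfig-class].
#' @param threshold absolute envelope threshold in uV, or NULL.
#' @return list with `count` and `events` (data.frame of start/end seconds,
#'   by onset).
#' @export
detectSpindles <- function(x, fs, config = defaultStagerConfig(),
                           threshold = NULL) {
  th <- thresholds(config)
  env <- slidingRms(butterFilt(x, fs, lo = config@bands$sigma[1],
                               hi = config@bands$sigma[2]),
                    k = round(0.25 * fs))
  if (is.null(threshold))
    threshold <- th[["spindle_threshold_k"]] * stats::median(env)
  # the 0.25-s RMS window widens each crossing by about its own length,
  # so the duration rule is applied to the smear-corrected duration
  ev <- runsAboveThreshold(env > threshold & threshold > 0, fs,
                           th[["spindle_min_dur"]] + 0.25,
                           th[["spindle_max_dur"]] + 0.25)
  list(count = nrow(ev), events = ev, threshold = threshold)
}

#' Detect arousals over an epoch sequence
#'
#' An arousal is an abrupt rise of combined alpha+beta power to at least
#' `arousal_threshold_k` times a trailing baseline, with a concurrent EMG
#' rise, sustained between the configured duration bounds. Power is tracked
#' in 1-s windows stepped by 0.5 s; the baseline is the median of the
#' preceding 60 s of windows. Events are attributed to the epoch containing
#' their onset (NAR); LAR is the total arousal seconds overlapping each
#' epoch.
#'
#' @param x numeric samples of the contiguous record.
#' @param fs sampling rate, Hz.
#' @param config a [StagerConfig-class].
#' @param epochLength epoch length, seconds.
#' @return list with per-epoch `nar` and `lar` vectors and `events`.
#' @export
detectArousals <- function(x, fs, config = defaultStagerConfig(),
                           epochLength = 30) {
  th <- thresholds(config)
  win <- round(1 * fs); step <- round(0.5 * fs)
  nEp <- floor(length(x) / (epochLength * fs))
  nar <- integer(nEp); lar <- numeric(nEp)
  empty <- list(nar = nar, lar = lar,
                events = data.frame(start = numeric(), end = numeric()))
  if (length(x) < 2 * win) return(empty)

  ab <- butterFilt(x, fs, lo = config@bands$alpha[1], hi = config@bands$beta[2])
  em <- butterFilt(x, fs, lo = emgBand(config)[1], hi = emgBand(config)[2])
  starts <- seq(1, length(x) - win + 1, by = step)
  csAb <- c(0, cumsum(ab^2)); csEm <- c(0, cumsum(em^2))
  pAb <- (csAb[starts + win] - csAb[starts]) / win
  pEm <- (csEm[starts + win] - csEm[starts]) / win

  nW <- length(starts)
  base <- 120L                     # trailing windows in the baseline (60 s)
  bAb <- numeric(nW); bEm <- numeric(nW)
  gAb <- stats::median(pAb); gEm <- stats::median(pEm)
  for (i in seq_len(nW)) {
    j0 <- max(1, i - base)
    if (i - j0 >= 10) {
      bAb[i] <- stats::median(pAb[j0:(i - 1)])
      bEm[i] <- stats::median(pEm[j0:(i - 1)])
    } else {
      bAb[i] <- gAb; bEm[i] <- gEm
    }
  }
  k <- th[["arousal_threshold_k"]]
  hot <- pAb >= k * pmax(bAb, 1e-12) & pEm >= 1.5 * pmax(bEm, 1e-12)

  r <- rle(hot)
  ends <- cumsum(r$lengths); starts_r <- ends - r$lengths + 1
  # a 1-s analysis window smears a power shift by about one window length;
  # the duration rule uses the smear-corrected duration (first-to-last
  # hot-window start), while the reported interval keeps the covered time
  durs <- (r$lengths - 1) * 0.5
  keep <- r$values & durs >= th[["arousal_min_dur"]] &
    durs <= th[["arousal_max_dur"]]
  ev <- data.frame(
    start = (starts[starts_r[keep]] - 1) / fs,
    end = (starts[ends[keep]] - 1 + win) / fs)

  if (nrow(ev)) {
    onEp <- pmin(nEp, floor(ev$start / epochLength) + 1)
    for (i in seq_len(nrow(ev))) {
      nar[onEp[i]] <- nar[onEp[i]] + 1L
      for (e in seq_len(nEp)) {
        ov <- min(ev$end[i], e * epochLength) -
          max(ev$start[i], (e - 1) * epochLength)
        if (ov > 0) lar[e] <- lar[e] + ov
      }
    }
    lar <- pmin(lar, epochLength)
  }
  list(nar = nar, lar = lar, events = ev)
}

#' Detect and classify eye-movement events
#'
#' The signal is low-passed at 6 Hz (removing spindles and EMG); maximal
#' runs where the absolute filtered amplitude exceeds `em_amplitude` for at
#' least 0.1 s are events. Each event is classified by its peak slope:
#' rapid (>= `em_slope_cutoff` uV/s; rapid eye movements of REM) versus
#' slow (blinks and slow rolling eye movements).
#'
#' @param x numeric epoch samples (difference signal).
#' @param fs sampling rate, Hz.
#' @param config a [StagerConfig-class].
#' @return list with `rapid` and `slow` counts and `events`.
#' @export
detectEyeMovements <- function(x, fs, config = defaultStagerConfig()) {
  th <- thresholds(config)
  xf <- butterFilt(x, fs, hi = 6, order = 3)
  ev <- runsAboveThreshold(abs(xf) >= th[["em_amplitude"]], fs, minDur = 0.1)
  if (!nrow(ev))
    return(list(rapid = 0L, slow = 0L,
                events = cbind(ev, slope = numeric(0))))
  slopes <- vapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1, round(ev$start[i] * fs) - round(0.25 * fs))
    i1 <- min(length(xf) - 1, round(ev$end[i] * fs) + round(0.25 * fs))
    max(abs(diff(xf[i0:i1]))) * fs
  }, numeric(1))
  rapid <- slopes >= th[["em_slope_cutoff"]]
  list(rapid = sum(rapid), slow = sum(!rapid),
       events = cbind(ev, slope = slopes))
}

## ---------------------------------------------------------------------------
## per-epoch feature table

#' Extract the per-epoch feature table
#'
#' Computes, for every epoch: the five EEG band powers and the EMG-band
#' power (Welch, 2-s Hamming windows, 50% overlap), the delta and alpha
#' fractions of summed EEG band power, the SBI/DBI/BEI/EMI ratios, spindle
#' count (NSP, against a record-wide sigma-envelope threshold), arousal
#' count and length (NAR/LAR, onset-attributed), rapid/slow eye-movement
#' counts, and the trailing 3-epoch arousal count (`nar3`) consulted by the
#' wake gate.
#'
#' @param epoched an [EpochedSignal-class] (the differential staging signal).
#' @param config a [StagerConfig-class].
#' @return data.frame with one row per epoch.
#' @export
extractFeatures <- function(epoched, config = defaultStagerConfig()) {
  fs <- samplingRate(epoched)
  nEp <- nEpochs(epoched)
  epLen <- epochLength(epoched)
  x <- as.numeric(epoched@epochs)

  emgTop <- min(emgBand(config)[2], fs / 2)
  allBands <- c(config@bands, list(emg = c(emgBand(config)[1], emgTop)))
  kMed <- round(0.25 * fs); if (kMed %% 2 == 0) kMed <- kMed + 1

  bp <- matrix(NA_real_, nEp, length(allBands),
               dimnames = list(NULL, names(allBands)))
  deltaMed <- numeric(nEp)
  for (e in seq_len(nEp)) {
    ep <- epochSamples(epoched, e)
    bp[e, ] <- bandPowers(ep, fs, allBands)
    med <- stats::runmed(ep, kMed, endrule = "constant")
    deltaMed[e] <- bandPowers(med, fs, allBands["delta"])[[1]]
  }

  eegCols <- c("delta", "theta", "alpha", "sigma", "beta")
  totEeg <- rowSums(bp[, eegCols, drop = FALSE])
  deltaFraction <- guardedRatio(bp[, "delta"], totEeg)
  alphaFraction <- guardedRatio(bp[, "alpha"], totEeg)

  sbi <- guardedRatio(bp[, "sigma"], bp[, "beta"])
  dbi <- guardedRatio(bp[, "delta"], bp[, "beta"])
  bei <- guardedRatio(bp[, "beta"], bp[, "emg"])
  emi <- guardedRatio(bp[, "delta"], deltaMed)

  # record-wide spindle threshold, then per-epoch counts by onset
  th <- thresholds(config)
  env <- slidingRms(butterFilt(x, fs, lo = config@bands$sigma[1],
                               hi = config@bands$sigma[2]),
                    k = round(0.25 * fs))
  spTh <- th[["spindle_threshold_k"]] * stats::median(env)
  spEv <- runsAboveThreshold(env > spTh & spTh > 0, fs,
                             th[["spindle_min_dur"]] + 0.25,
                             th[["spindle_max_dur"]] + 0.25)
  nsp <- integer(nEp)
  if (nrow(spEv)) {
    onEp <- pmin(nEp, floor(spEv$start / epLen) + 1)
    for (e in onEp) nsp[e] <- nsp[e] + 1L
  }

  ar <- detectArousals(x, fs, config, epochLength = epLen)

  rapidEm <- integer(nEp); slowEm <- integer(nEp)
  for (e in seq_len(nEp)) {
    em <- detectEyeMovements(epochSamples(epoched, e), fs, config)
    rapidEm[e] <- em$rapid; slowEm[e] <- em$slow
  }

  nar3 <- vapply(seq_len(nEp), function(e)
    sum(ar$nar[max(1, e - 2):e]), numeric(1))

  data.frame(
    epoch = seq_len(nEp),
    delta = bp[, "delta"], theta = bp[, "theta"], alpha = bp[, "alpha"],
    sigma = bp[, "sigma"], beta = bp[, "beta"], emg = bp[, "emg"],
    totalEeg = totEeg, deltaFraction = deltaFraction,
    alphaFraction = alphaFraction,
    sbi = sbi, dbi = dbi, bei = bei, emi = emi,
    nsp = nsp, nar = ar$nar, lar = ar$lar,
    rapidEm = rapidEm, slowEm = slowEm, nar3 = nar3,
    row.names = NULL
  )
}

#' Write a per-epoch feature table to CSV
#'
#' @param features data.frame from [extractFeatures()].
#' @param path output CSV path.
#' @export
writeFeatures <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
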
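## Synthetic polysomnography: truth hypnograms (Markov chain at epoch
## scale), matching two-channel EOG signals whose difference carries
## stage-dependent spectral content and events, and Poisson respiratory
## event lists, so the whole pipeline is testable without recorded data.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Severity profiles for sleep-disordered breathing
#'
#' Each profile carries the mean respiratory disturbance index of its
#' severity class (6, 15, 31 and 71 events/hour for normal, mild, moderate
#' and severe), the target stage distribution (pooled normal/mild and
#' moderate/severe epoch fractions from the validation cohort's
#' cross-tabulations; the moderate/severe fractions are derived from the
#' row epoch counts), and an arousal-rate multiplier.
#'
#' @param severity "normal", "mild", "moderate" or "severe".
#' @return an [SdbProfile-class].
#' @examples
#' sdbProfile("severe")
#' @export
sdbProfile <- function(severity = c("normal", "mild", "moderate", "severe")) {
  severity <- match.arg(severity)
  rdi <- c(normal = 6, mild = 15, moderate = 31, severe = 71)[[severity]]
  fr <- if (severity %in% c("normal", "mild")) {
    c(0.181, 0.134, 0.447, 0.104, 0.134)
  } else {
    # row epoch counts (9086, 6955, 10205, 1077, 2615) / 29938
    c(9086, 6955, 10205, 1077, 2615) / 29938
  }
  mult <- c(normal = 1, mild = 1, moderate = 2, severe = 3)[[severity]]
  new("SdbProfile", severity = severity, targetRdi = rdi,
      stageFractions = fr / sum(fr), arousalMultiplier = mult)
}

#' Build a Markov hypnogram model from a severity profile
#'
#' Constructs a reversible transition matrix whose stationary distribution
#' equals the profile's stage fractions exactly, with mean bout lengths
#' close to a default table (W 4, N1 2, N2 12, N3 8, REM 16 epochs). The
#' construction sets the inter-stage flow from s to t proportional to
#' e_s e_t, where e_s = pi_s / L_s is the requested exit flow; row sums of
#' the flow then come out slightly below e_s, so realized bouts are
#' marginally longer than requested while stationarity is exact.
#'
#' @param profile an [SdbProfile-class].
#' @param nEpochs number of epochs the model will generate.
#' @param boutEpochs mean bout length per stage, in epochs.
#' @return a [HypnogramModel-class].
#' @export
profileToModel <- function(profile, nEpochs = 960,
                           boutEpochs = c(W = 4, N1 = 2, N2 = 12,
                                          N3 = 8, R = 16)) {
  pi0 <- profile@stageFractions
  if (sum(pi0) <= 0) stop("profileToModel: infeasible stage fractions")
  e <- ifelse(pi0 > 0, pi0 / boutEpochs[STAGES], 0)
  E <- sum(e)
  P <- diag(5)
  if (E > 0) {
    for (s in 1:5) {
      if (pi0[s] == 0) next
      for (t in 1:5) {
        if (t == s || pi0[t] == 0) next
        P[s, t] <- e[s] * e[t] / (E * pi0[s])
      }
      P[s, s] <- 1 - sum(P[s, -s])
    }
  }
  hypnogramModel(P, initial = pi0, nEpochs = nEpochs)
}

#' Simulate a hypnogram from a Markov model
#'
#' @param model a [HypnogramModel-class].
#' @param seed RNG seed for reproducibility (NULL uses the current RNG
#'   state).
#' @param epochLength epoch length in seconds.
#' @return a [Hypnogram-class] of `model@nEpochs` epochs.
#' @export
simulateHypnogram <- function(model, seed = NULL, epochLength = 30) {
  validObject(model)
  withSeed(seed, {
    n <- model@nEpochs
    idx <- integer(n)
    idx[1] <- sample.int(5, 1, prob = model@initial)
    if (n > 1) for (i in 2:n)
      idx[i] <- sample.int(5, 1, prob = model@transition[idx[i - 1], ])
    hypnogram(STAGES[idx], epochLength = epochLength)
  })
}

#' Stage-dependent synthesis parameters
#'
#' Default amplitudes are RMS microvolts of the difference (REOG-LEOG)
#' signal per band, chosen to mimic the qualitative spectral signatures of
#' the five stages: alpha + high EMG + blinks in W, theta in N1, spindles
#' over mixed background in N2, dominant slow waves in N3, theta + rapid
#' eye movements + EMG atonia in REM. `contrast` interpolates every
#' stage-specific amplitude toward the across-stage mean and scales event
#' rates: 1 is the full-contrast preset, 0 removes all stage information
#' (every epoch statistically identical, no events).
#'
#' @param contrast stage-separability dial in `[0, 1]`.
#' @param sampleRate output rate, 128 (default, exercising the resampling
#'   path) or 256 Hz.
#' @return a [SynthesisParams-class].
#' @export
synthesisParams <- function(contrast = 1, sampleRate = 128) {
  stopifnot(contrast >= 0, contrast <= 1)
  A <- rbind(  # delta theta alpha sigma beta  (RMS uV of the difference)
    W  = c(10,  5, 22, 4, 8),
    N1 = c( 8, 12,  6, 3, 4),
    N2 = c(15, 10,  5, 6, 4),
    N3 = c(20,  8,  4, 3, 2.5),
    R  = c( 8, 14,  5, 2, 5))
  colnames(A) <- c("delta", "theta", "alpha", "sigma", "beta")
  emg <- c(W = 6, N1 = 2, N2 = 2, N3 = 1.5, R = 0.7)
  blend <- function(v) {
    m <- mean(v); m + contrast * (v - m)
  }
  A <- apply(A, 2, blend); rownames(A) <- STAGES
  new("SynthesisParams",
      bandAmp = A, emgAmp = blend(emg),
      spindleRate = 3 * contrast, spindleAmp = 30 * contrast,
      remRate = 3 * contrast, remAmp = 150 * contrast,
      blinkRate = 6 * contrast, blinkAmp = 150 * contrast,
      sharedAmp = 15, noiseFloor = 1, sampleRate = sampleRate)
}

## band-limited unit-RMS Gaussian noise via FFT masking
bandNoise <- function(n, fs, lo, hi) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # fold to [0, fs/2]
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x / s
}

triangle <- function(nUp, nDown, amp) {
  c(seq(0, amp, length.out = nUp + 1)[-1],
    seq(amp, 0, length.out = nDown + 1)[-1])
}

addEvent <- function(x, at, shape) {
  i0 <- at; i1 <- min(length(x), at + length(shape) - 1)
  if (i0 > length(x)) return(x)
  x[i0:i1] <- x[i0:i1] + shape[seq_len(i1 - i0 + 1)]
  x
}

#' Synthesize a two-channel EOG recording for a hypnogram
#'
#' Per epoch, the difference signal is a sum of band-limited Gaussian noise
#' with stage-specific RMS amplitudes plus stage-specific events: spindle
#' bursts (13 Hz, Hann envelope) in N2, high-amplitude slow waves in N3
#' (via the delta amplitude), conjugate rapid deflections in REM, slow
#' blink deflections in W, and EMG-band noise modulated per stage.
#' Eye-movement and other difference components are split anti-phase across
#' the two channels (so they add in the difference), while a shared
#' cerebral component enters both channels in phase and cancels. Optional
#' `arousalTimes` inject 5-s alpha + EMG bursts (cortical arousals).
#'
#' @param h a [Hypnogram-class] (truth stages).
#' @param params a [SynthesisParams-class].
#' @param seed RNG seed.
#' @param arousalTimes onset times (s) of arousal bursts, or NULL.
#' @return list of two [RawChannel-class] objects, `left` and `right`.
#' @export
synthesizeSignal <- function(h, params = synthesisParams(), seed = NULL,
                             arousalTimes = NULL) {
  validObject(params)
  fs <- params@sampleRate
  epLen <- epochLength(h)
  spe <- round(epLen * fs)
  n <- nEpochs(h)
  N <- n * spe
  stgIdx <- match(stages(h), STAGES)

  withSeed(seed, {
    bands <- defaultBands()
    perSample <- rep(stgIdx, each = spe)
    d <- numeric(N)
    for (b in seq_along(bands)) {
      u <- bandNoise(N, fs, bands[[b]][1], bands[[b]][2])
      d <- d + u * params@bandAmp[perSample, b]
    }
    emgLo <- 32; emgHi <- min(64, fs / 2 * 0.999)
    emgL <- bandNoise(N, fs, emgLo, emgHi) * params@emgAmp[perSample] / sqrt(2)
    emgR <- bandNoise(N, fs, emgLo, emgHi) * params@emgAmp[perSample] / sqrt(2)

    # stage-specific events, added to the difference component
    for (e in seq_len(n)) {
      off <- (e - 1) * spe
      st <- stages(h)[e]
      if (st == "N2" && params@spindleRate > 0) {
        for (k in seq_len(stats::rpois(1, params@spindleRate))) {
          dur <- stats::runif(1, 0.7, 1.3)
          len <- round(dur * fs)
          t <- seq_len(len) / fs
          shape <- params@spindleAmp * sin(2 * pi * 13 * t) *
            0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
          at <- off + sample.int(spe - len, 1)
          d <- addEvent(d, at, shape)
        }
      } else if (st == "R" && params@remRate > 0) {
        for (k in seq_len(stats::rpois(1, params@remRate))) {
          shape <- triangle(round(0.2 * fs), round(0.2 * fs),
                            sample(c(-1, 1), 1) * params@remAmp)
          at <- off + sample.int(spe - length(shape), 1)
          d <- addEvent(d, at, shape)
        }
      } else if (st == "W" && params@blinkRate > 0) {
        for (k in seq_len(stats::rpois(1, params@blinkRate))) {
          shape <- triangle(round(2 * fs), round(2 * fs), params@blinkAmp)
          at <- off + sample.int(max(1, spe - length(shape)), 1)
          d <- addEvent(d, at, shape)
        }
      }
    }

    if (!is.null(arousalTimes) && length(arousalTimes)) {
      alphaU <- bandNoise(N, fs, 8, 12)
      emgU <- bandNoise(N, fs, emgLo, emgHi)
      for (t0 in arousalTimes) {
        idx <- round(t0 * fs) + seq_len(round(5 * fs))
        idx <- idx[idx >= 1 & idx <= N]
        if (!length(idx)) next
        d[idx] <- d[idx] + 10 * alphaU[idx]
        emgL[idx] <- emgL[idx] + 4 * emgU[idx]
        emgR[idx] <- emgR[idx] + 4 * emgU[idx]
      }
    }

    shared <- bandNoise(N, fs, 0.75, min(32, fs / 2 * 0.99)) * params@sharedAmp
    left <- shared - d / 2 + emgL + stats::rnorm(N, sd = params@noiseFloor)
    right <- shared + d / 2 + emgR + stats::rnorm(N, sd = params@noiseFloor)
    list(left = rawChannel(left, fs, "LEOG"),
         right = rawChannel(right, fs, "REOG"))
  })
}

#' Simulate a respiratory event list
#'
#' A homogeneous Poisson process at the profile's RDI (events per hour of
#' sleep) over the hypnogram's non-wake epochs; event times fall only
#' inside sleep epochs.
#'
#' @param h a [Hypnogram-class].
#' @param profile an [SdbProfile-class].
#' @param seed RNG seed.
#' @return a `"RespiratoryEvents"` object (see [respiratoryEvents()]).
#' @export
simulateRespiratoryEvents <- function(h, profile, seed = NULL) {
  sleepEp <- which(stages(h) != "W")
  epLen <- epochLength(h)
  hours <- length(sleepEp) * epLen / 3600
  withSeed(seed, {
    count <- stats::rpois(1, profile@targetRdi * hours)
    if (count == 0 || !length(sleepEp))
      return(respiratoryEvents(times = numeric()))
    ep <- sample(sleepEp, count, replace = TRUE)
    times <- sort((ep - 1) * epLen + stats::runif(count, 0, epLen))
    respiratoryEvents(times = times)
  })
}

#' Write a self-contained synthetic PSG fixture
#'
#' Generates a truth hypnogram, the matching two-channel EOG EDF, and a
#' respiratory-event list; a random subset of respiratory events (scaled by
#' the profile's arousal multiplier) additionally triggers an arousal burst
#' in the signal. Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if missing).
#' @param profile an [SdbProfile-class].
#' @param params a [SynthesisParams-class].
#' @param nEpochs number of 30-s epochs.
#' @param seed integer seed; sub-seeds are derived from it.
#' @return named list: paths `edf`, `hypnogramCsv`, `eventsCsv`, plus the
#'   truth `hypnogram` object.
#' @export
writeFixture <- function(dir, profile = sdbProfile("normal"),
                         params = synthesisParams(), nEpochs = 960,
                         seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- profileToModel(profile, nEpochs = nEpochs)
  h <- simulateHypnogram(model, seed = seed)
  events <- simulateRespiratoryEvents(h, profile, seed = seed + 1)
  arTimes <- withSeed(seed + 2, {
    if (!is.null(events$times) && length(events$times)) {
      p <- min(1, 0.3 * profile@arousalMultiplier)
      events$times[stats::runif(length(events$times)) < p] + 1
    } else numeric()
  })
  sig <- synthesizeSignal(h, params, seed = seed + 3, arousalTimes = arTimes)
  paths <- list(edf = file.path(dir, "psg.edf"),
                hypnogramCsv = file.path(dir, "hypnogram.csv"),
                eventsCsv = file.path(dir, "events.csv"))
  writeEdf(list(sig$left, sig$right), paths$edf)
  writeHypnogram(h, paths$hypnogramCsv)
  writeRespiratoryEvents(events, paths$eventsCsv)
  c(paths, list(hypnogram = h))
}
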
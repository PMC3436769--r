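# Shared fixture builders. Everything is generated in code at test time.

# a channel carrying a pure tone (plus optional noise), in microvolts
toneChannel <- function(freqHz, seconds = 30, fs = 256, amp = 10,
                        noiseSd = 0, label = "tone", seed = 1) {
  n <- round(seconds * fs)
  t <- (seq_len(n) - 1) / fs
  x <- amp * sin(2 * pi * freqHz * t)
  if (noiseSd > 0) x <- x + withr::with_seed(seed, rnorm(n, sd = noiseSd))
  rawChannel(x, fs, label)
}

# white Gaussian background, in microvolts
noiseChannel <- function(seconds = 30, fs = 256, sd = 5, seed = 1,
                         label = "noise") {
  n <- round(seconds * fs)
  rawChannel(withr::with_seed(seed, rnorm(n, sd = sd)), fs, label)
}

# a triangular deflection: linear rise and fall, peak `amp` uV
deflection <- function(riseSec, amp, fs = 256) {
  n <- round(riseSec * fs)
  c(seq(0, amp, length.out = n + 1)[-1], seq(amp, 0, length.out = n + 1)[-1])
}

# small random 5x5 contingency tables for kappa property tests
randomTable <- function(maxCount = 50) {
  matrix(sample.int(maxCount + 1, 25, replace = TRUE) - 1L, 5, 5,
         dimnames = list(manual = STAGES, auto = STAGES))
}

# independent brute-force 2x2 Cohen's kappa used as the oracle:
# builds the collapsed table cellwise and applies the definition directly
bruteForceKappa <- function(tab, stageIdx) {
  n <- sum(tab)
  a <- matrix(0, 2, 2)
  for (i in 1:5) for (j in 1:5) {
    r <- if (i == stageIdx) 1 else 2
    c <- if (j == stageIdx) 1 else 2
    a[r, c] <- a[r, c] + tab[i, j]
  }
  po <- (a[1, 1] + a[2, 2]) / n
  pe <- (sum(a[1, ]) * sum(a[, 1]) + sum(a[2, ]) * sum(a[, 2])) / n^2
  if (pe == 1) 0 else (po - pe) / (1 - pe)
}

# a short high-contrast synthetic record staged end to end
stageSynthetic <- function(nEpochs, seed, contrast = 1,
                           profile = sdbProfile("normal"),
                           config = defaultStagerConfig()) {
  model <- profileToModel(profile, nEpochs = nEpochs)
  h <- simulateHypnogram(model, seed = seed)
  sig <- synthesizeSignal(h, synthesisParams(contrast), seed = seed + 1)
  d <- resampleLinear(deriveStagingSignal(sig$left, sig$right), 256)
  res <- stageRecord(epochSignal(d, 30), config)
  list(truth = h, auto = res$hypnogram, features = res$features,
       decisions = res$decisions)
}

stageRecovery <- function(truth, auto) {
  tab <- confusionMatrix(truth, auto)
  100 * diag(tab) / pmax(rowSums(tab), 1)
}
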
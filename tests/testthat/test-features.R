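test_that("band powers vanish on silence and concentrate for a pure tone", {
  bands <- c(list(delta = c(0.75, 4), theta = c(4, 8), alpha = c(8, 12),
                  sigma = c(12, 16), beta = c(16, 32)),
             list(emg = c(32, 64)))
  zero <- bandPowers(numeric(7680), 256, bands)
  expect_true(all(zero == 0))

  tone <- channelSamples(toneChannel(10, 30, 256, amp = 20))
  bp <- bandPowers(tone, 256, bands)
  expect_gt(bp[["alpha"]] / sum(bp), 0.90)

  # Parseval bound: integrated band power cannot exceed total signal power
  withr::with_seed(7, x <- rnorm(7680, sd = 12))
  bp <- bandPowers(x, 256, bands)
  expect_lte(sum(bp), stats::var(x) * 1.05)
  # and a tone's alpha power recovers its variance closely
  expect_equal(bandPowers(tone, 256, bands)[["alpha"]], stats::var(tone),
               tolerance = 0.02)
})

test_that("band edges above Nyquist are rejected", {
  expect_error(bandPowers(rnorm(512), 128, list(emg = c(32, 128))), "Nyquist")
})

test_that("ratio features follow their definitions with guarded division", {
  r <- computeRatios(c(delta = 4, theta = 1, alpha = 1, sigma = 3, beta = 3),
                     emgPower = 1.5, deltaFiltered = 4)
  expect_equal(r[["sbi"]], 1)
  expect_equal(r[["dbi"]], 4 / 3)
  expect_equal(r[["bei"]], 2)
  expect_equal(r[["emi"]], 1)   # epoch unchanged by the median filter

  z <- computeRatios(c(delta = 0, theta = 0, alpha = 0, sigma = 0, beta = 0),
                     emgPower = 0, deltaFiltered = 0)
  expect_true(all(z[c("sbi", "dbi", "bei", "emi")] == 0))
})

test_that("spindle detection requires threshold crossing and duration", {
  cfg <- defaultStagerConfig()
  expect_equal(detectSpindles(numeric(7680), 256, cfg)$count, 0)

  withr::with_seed(21, bg <- rnorm(7680, sd = 3))
  burst <- 5 * 3 * sqrt(2) * sin(2 * pi * 13 * seq_len(256) / 256)  # 1.0 s, 5x RMS
  x <- bg; x[2000 + seq_along(burst)] <- x[2000 + seq_along(burst)] + burst
  det <- detectSpindles(x, 256, cfg)
  expect_equal(det$count, 1)
  expect_equal(det$events$start, 2000 / 256, tolerance = 0.15)

  short <- bg
  shortBurst <- burst[seq_len(round(0.2 * 256))]
  short[2000 + seq_along(shortBurst)] <- short[2000 + seq_along(shortBurst)] +
    shortBurst
  expect_equal(detectSpindles(short, 256, cfg)$count, 0)
})

test_that("spindle detection is translation-equivariant", {
  cfg <- defaultStagerConfig()
  withr::with_seed(22, bg <- rnorm(7680 * 2, sd = 3))
  burst <- 5 * 3 * sqrt(2) * sin(2 * pi * 13 * seq_len(256) / 256)
  at <- function(offset) {
    x <- bg; idx <- offset + seq_along(burst)
    x[idx] <- x[idx] + burst
    detectSpindles(x, 256, cfg)$events$start
  }
  expect_equal(at(3000 + 256) - at(3000), 1, tolerance = 0.05)
})

test_that("arousal detection finds sustained alpha+EMG shifts only", {
  cfg <- defaultStagerConfig()
  fs <- 256
  nEp <- 6
  mkRecord <- function(burstSec) {
    withr::with_seed(30, {
      x <- rnorm(nEp * 30 * fs, sd = 4)
      if (burstSec > 0) {
        t <- seq_len(round(burstSec * fs)) / fs
        idx <- (30 * 3 + 1) * fs + seq_along(t)  # onset 1 s into epoch 4
        x[idx] <- x[idx] + 15 * sin(2 * pi * 10 * t) +
          rnorm(length(t), sd = 8)               # alpha + broadband/EMG rise
      }
      x
    })
  }
  quiet <- detectArousals(mkRecord(0), fs, cfg)
  expect_equal(sum(quiet$nar), 0)
  expect_equal(sum(quiet$lar), 0)

  hit <- detectArousals(mkRecord(5), fs, cfg)
  expect_equal(sum(hit$nar), 1)
  expect_equal(hit$nar[4], 1)
  expect_equal(sum(hit$lar), 5, tolerance = 1.5)

  short <- detectArousals(mkRecord(2), fs, cfg)
  expect_equal(sum(short$nar), 0)
})

test_that("eye movements are classified rapid vs slow by peak slope", {
  cfg <- defaultStagerConfig()
  fs <- 256
  flat <- detectEyeMovements(numeric(30 * fs), fs, cfg)
  expect_equal(c(flat$rapid, flat$slow), c(0, 0))

  base <- withr::with_seed(31, rnorm(30 * fs, sd = 3))
  inject <- function(riseSec) {
    sh <- deflection(riseSec, 150, fs)
    x <- base; x[1000 + seq_along(sh)] <- x[1000 + seq_along(sh)] + sh
    detectEyeMovements(x, fs, cfg)
  }
  fast <- inject(0.2)    # 750 uV/s rise
  expect_equal(fast$rapid, 1)
  expect_equal(fast$slow, 0)

  slow <- inject(2)      # 75 uV/s rise
  expect_equal(slow$rapid, 0)
  expect_equal(slow$slow, 1)
})

test_that("feature extraction yields one row per epoch with local features", {
  withr::with_seed(40, ch <- rawChannel(rnorm(7680 * 10, sd = 10), 256, "d"))
  ep <- epochSignal(ch, 30)
  f <- extractFeatures(ep)
  expect_equal(nrow(f), 10)
  expect_true(all(c("delta", "sigma", "emg", "sbi", "dbi", "bei", "emi",
                    "nsp", "nar", "lar", "rapidEm", "slowEm") %in% names(f)))
  expect_true(all(f$lar <= 30))
  expect_true(all(f[c("delta", "theta", "alpha", "sigma", "beta", "emg")] >= 0))

  # permuting two epochs permutes their band-power rows (per-epoch locality)
  perm <- ep
  perm@epochs <- ep@epochs[, c(2, 1, 3:10)]
  fp <- extractFeatures(perm)
  powerCols <- c("delta", "theta", "alpha", "sigma", "beta", "emg")
  expect_equal(fp[1, powerCols], f[2, powerCols], ignore_attr = TRUE)
  expect_equal(fp[2, powerCols], f[1, powerCols], ignore_attr = TRUE)
})

test_that("all-zero records produce zero powers, counts and guarded ratios", {
  ep <- epochSignal(rawChannel(numeric(7680 * 2), 256, "d"), 30)
  f <- extractFeatures(ep)
  expect_true(all(f[c("delta", "emg", "sbi", "dbi", "bei",
                      "nsp", "nar", "rapidEm", "slowEm")] == 0))
})

test_that("amplitude scaling scales powers by c^2 and leaves ratios fixed", {
  withr::with_seed(41, x <- rnorm(7680 * 3, sd = 10))
  ep1 <- epochSignal(rawChannel(x, 256, "d"), 30)
  ep2 <- epochSignal(rawChannel(3 * x, 256, "d"), 30)
  f1 <- extractFeatures(ep1); f2 <- extractFeatures(ep2)
  powerCols <- c("delta", "theta", "alpha", "sigma", "beta", "emg")
  expect_equal(as.matrix(f2[powerCols]), 9 * as.matrix(f1[powerCols]),
               tolerance = 1e-10)
  for (col in c("sbi", "dbi", "bei", "emi", "deltaFraction", "alphaFraction"))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-10)
})

test_that("stage-pure synthetic epochs order DBI and NSP as expected", {
  # stage-pure blocks in one record, so the record-wide spindle threshold
  # is referenced to a realistic mixed background
  truth <- rep(c("N3", "N2", "W", "R"), each = 10)
  h <- hypnogram(truth)
  sig <- synthesizeSignal(h, synthesisParams(1, sampleRate = 256), seed = 50)
  d <- deriveStagingSignal(sig$left, sig$right)
  f <- extractFeatures(epochSignal(d, 30))
  byStage <- split(f, truth)
  expect_gt(median(byStage$N3$dbi), median(byStage$N2$dbi))
  expect_gt(median(byStage$N2$dbi), median(byStage$W$dbi))
  expect_gt(median(byStage$N2$nsp), median(byStage$N3$nsp))
  expect_gt(median(byStage$N2$nsp), median(byStage$R$nsp))
})
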
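test_that("the confusion table counts epochs and conserves the total", {
  withr::with_seed(70, {
    m <- hypnogram(sample(STAGES, 300, replace = TRUE))
    a <- hypnogram(sample(STAGES, 300, replace = TRUE))
  })
  tab <- confusionMatrix(m, a)
  expect_equal(sum(tab), 300)

  same <- confusionMatrix(m, m)
  expect_equal(sum(diag(same)), 300)
  expect_true(all(same[upper.tri(same) | lower.tri(same)] == 0))

  wOnly <- confusionMatrix(hypnogram(rep("W", 10)), hypnogram(rep("N1", 10)))
  expect_equal(wOnly["W", "N1"], 10L)
  expect_equal(sum(wOnly), 10)

  expect_error(confusionMatrix(m, hypnogram(rep("W", 10))), "lengths differ")
})

test_that("per-stage kappa matches the brute-force 2x2 oracle", {
  withr::with_seed(71, {
    for (i in 1:200) {
      tab <- randomTable()
      if (sum(tab) == 0) next
      for (s in 1:5)
        expect_equal(perStageKappa(tab, s), bruteForceKappa(tab, s),
                     tolerance = 1e-12)
    }
  })
})

test_that("kappa is 1 for diagonal tables and 0 under margin independence", {
  diagTab <- diag(c(5L, 7L, 11L, 3L, 9L))
  expect_true(all(perStageKappa(diagTab) == 1))

  # product table: rows proportional -> chance-level agreement exactly
  prod <- outer(c(1L, 2L, 3L, 4L, 5L), c(2L, 1L, 3L, 1L, 2L))
  expect_true(all(abs(perStageKappa(prod)) < 1e-12))

  # both raters constant: Pe = 1 guard returns 0
  const <- matrix(0L, 5, 5); const[2, 2] <- 50L
  expect_equal(perStageKappa(const, "N1"), 0)
  expect_error(perStageKappa(matrix(0L, 5, 5)), "empty")
})

test_that("percent agreement normalizes rows and reports the trace", {
  diagTab <- diag(c(5L, 7L, 11L, 3L, 9L))
  pa <- percentAgreement(diagTab)
  expect_true(all(pa$stagePercent == 100))
  expect_equal(pa$overall, 100)

  withr::with_seed(72, tab <- randomTable())
  pa <- percentAgreement(tab)
  expect_equal(unname(rowSums(pa$rowPercent)), rep(100, 5))
  expect_equal(pa$overall, 100 * sum(diag(tab)) / sum(tab))

  zeroRow <- diag(c(0L, 1L, 1L, 1L, 1L))
  expect_true(is.na(percentAgreement(zeroRow)$stagePercent[["W"]]))
})

test_that("count reconstruction inverts the printed-percentage format", {
  pub <- publishedAgreementTables()$normalMild
  tab <- reconstructCounts(pub$rowPercent, pub$rowTotals)
  expect_equal(tab["W", "W"], round(0.797 * 7342))   # 5852
  expect_equal(unname(rowSums(tab)), pub$rowTotals)
  expect_lte(abs(sum(tab[, "W"]) - pub$printedAutoTotals[1]), 5)

  simple <- matrix(0, 5, 5); simple[, 1] <- 100
  out <- reconstructCounts(simple, c(10, 0, 0, 0, 0))
  expect_equal(out[1, ], c(W = 10L, N1 = 0L, N2 = 0L, N3 = 0L, R = 0L))

  bad <- pub$rowPercent; bad[1, 1] <- bad[1, 1] + 5
  expect_error(reconstructCounts(bad, pub$rowTotals), "sum to 100")
})

test_that("ICC(2,1) matches the two-way mean-squares decomposition", {
  x <- c(10, 12, 8, 14); y <- c(11, 13, 9, 16)
  expect_equal(iccAbsolute(x, y), 0.897560975610, tolerance = 1e-10)

  # perfect agreement
  expect_equal(iccAbsolute(c(1, 5, 9), c(1, 5, 9)), 1)

  # a constant offset destroys absolute agreement though correlation is 1
  xo <- c(10, 20, 30, 40)
  expect_lt(iccAbsolute(xo, xo + 50), 0.2)
  expect_equal(stats::cor(xo, xo + 50), 1)

  # random-data equivalence against an aov-based oracle
  withr::with_seed(73, {
    for (i in 1:25) {
      n <- sample(4:20, 1)
      a <- rnorm(n, 100, 20); b <- a + rnorm(n, 2, 5)
      d <- data.frame(v = c(a, b), s = factor(rep(seq_len(n), 2)),
                      r = factor(rep(1:2, each = n)))
      ms <- stats::anova(stats::lm(v ~ s + r, d))$`Mean Sq`
      oracle <- (ms[1] - ms[3]) /
        (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / n)
      expect_equal(iccAbsolute(a, b), oracle, tolerance = 1e-10)
    }
  })

  expect_error(iccAbsolute(1:2, 1:2), ">= 3")
  expect_error(iccAbsolute(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("sensitivity and PPV respect the 20-epoch inclusion floor", {
  withr::with_seed(74, m <- hypnogram(sample(STAGES, 200, replace = TRUE)))
  r <- sensitivityPpv(m, m, "N2")
  expect_equal(c(r$sensitivity, r$ppv), c(100, 100))
  expect_false(r$excluded)

  few <- hypnogram(c(rep("N3", 19), rep("N2", 81)))
  expect_true(sensitivityPpv(few, few, "N3")$excluded)

  neverAuto <- hypnogram(rep("N2", 100))
  manualR <- hypnogram(c(rep("R", 30), rep("N2", 70)))
  r2 <- sensitivityPpv(manualR, neverAuto, "R")
  expect_equal(r2$sensitivity, 0)
  expect_true(is.na(r2$ppv))
})

test_that("sleep onset is the first run of three consecutive non-wake epochs", {
  expect_equal(sleepOnset(hypnogram(c("W", "W", "N1", "N1", "N1", "W"))), 3)
  expect_true(is.na(sleepOnset(hypnogram(rep("W", 10)))))
  expect_true(is.na(sleepOnset(hypnogram(c("N1", "W", "N1", "N1", "W", "N2",
                                           "N1", "W")))))
  # invariant to appending epochs after the detected onset
  base <- c("W", "N1", "N2", "N3")
  on <- sleepOnset(hypnogram(base))
  expect_equal(on, 2)
  withr::with_seed(75, {
    for (i in 1:20) {
      ext <- c(base, sample(STAGES, sample(1:30, 1), replace = TRUE))
      expect_equal(sleepOnset(hypnogram(ext)), on)
    }
  })
})

test_that("onset differences bin at 3, 10 and 20 minutes", {
  expect_equal(onsetDifferenceBin(10, 10), "<=3")
  expect_equal(onsetDifferenceBin(1, 7), "<=3")       # exactly 3.0 min
  expect_equal(onsetDifferenceBin(1, 21), "4-10")     # 10.0 min in (3,10]
  expect_equal(onsetDifferenceBin(1, 22), "11-20")    # 10.5 min
  expect_equal(onsetDifferenceBin(1, 41), "11-20")    # 20.0 min
  expect_equal(onsetDifferenceBin(1, 42), ">20")      # 20.5 min
  expect_true(is.na(onsetDifferenceBin(NA, 5)))
})

test_that("sleep summaries compute TST, efficiency and RDI", {
  h <- hypnogram(c(rep("W", 120), rep("N2", 600)))    # 720 epochs, 600 asleep
  s <- sleepSummary(h, recordingMinutes = 360)
  expect_equal(s$tstMinutes, 300)
  expect_equal(s$sleepEfficiency, 100 * 300 / 360, tolerance = 1e-12)

  s2 <- sleepSummary(h, 360, respiratoryEvents(count = 150))
  expect_equal(s2$rdi, 30)

  sW <- sleepSummary(hypnogram(rep("W", 10)))
  expect_true(sW$rdiUndefined)
  expect_true(is.na(sW$rdi))
  expect_error(sleepSummary(h, recordingMinutes = 100), "shorter")
})

test_that("Bland-Altman bias and limits use twice the SD of differences", {
  same <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$lower, same$upper), c(0, 0, 0))

  off <- blandAltman(c(10, 20, 30), c(15, 25, 35))
  expect_equal(off$bias, 5)
  expect_equal(off$sdDiff, 0)

  withr::with_seed(76, {
    m <- rnorm(30, 300, 40); a <- m + rnorm(30, -5, 25)
    ba <- blandAltman(m, a)
    expect_equal(ba$bias, mean(a - m), tolerance = 1e-12)
    expect_equal(ba$sdDiff, sd(a - m), tolerance = 1e-12)
    expect_equal(ba$upper - ba$lower, 4 * sd(a - m), tolerance = 1e-12)
  })
  expect_error(blandAltman(1, 2), ">= 2")
})

test_that("the full agreement report is internally consistent", {
  withr::with_seed(77, {
    m <- hypnogram(sample(STAGES, 400, replace = TRUE,
                          prob = c(.2, .15, .4, .1, .15)))
    flip <- runif(400) < 0.2
    a <- stages(m)
    a[flip] <- sample(STAGES, sum(flip), replace = TRUE)
  })
  rep <- agreementReport(m, hypnogram(a))
  expect_equal(sum(rep@confusion), 400)
  expect_true(all(rep@kappa >= -1 & rep@kappa <= 1))
  expect_equal(rep@overallPercent, 100 * mean(stages(m) == a))
  expect_equal(unname(rep@sensitivity), unname(diag(rep@rowPercent)))
})
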
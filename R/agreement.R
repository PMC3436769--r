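## Manual-vs-automated agreement statistics: confusion tables, one-vs-rest
## Cohen's kappa, percent agreement, count reconstruction from printed
## percentage tables, ICC(2,1), per-subject sensitivity/PPV, sleep onset,
## TST/SE/RDI summaries and Bland-Altman limits.

#' Epoch-by-epoch confusion table
#'
#' @param manual,auto [Hypnogram-class] objects of equal length; rows of
#'   the result are the manual stage, columns the automated stage, in
#'   [STAGES] order.
#' @return 5x5 integer matrix.
#' @export
confusionMatrix <- function(manual, auto) {
  m <- stages(manual); a <- stages(auto)
  if (length(m) != length(a))
    stop("confusionMatrix: hypnogram lengths differ (", length(m), " vs ",
         length(a), ")")
  tab <- table(factor(m, levels = STAGES), factor(a, levels = STAGES))
  matrix(as.integer(tab), 5, 5, dimnames = list(manual = STAGES,
                                                auto = STAGES))
}

collapse2x2 <- function(tab, stage) {
  s <- if (is.character(stage)) match(stage, STAGES) else stage
  tp <- tab[s, s]
  fn <- sum(tab[s, -s]); fp <- sum(tab[-s, s]); tn <- sum(tab[-s, -s])
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-stage Cohen's kappa (one-vs-rest collapse)
#'
#' The 5x5 table is collapsed to 2x2 (stage vs not-stage for both raters)
#' and Cohen's kappa computed as (Po - Pe) / (1 - Pe), with Po the observed
#' proportion agreeing and Pe the chance agreement from the margins.
#' Returns 0 when Pe = 1 (both raters constant).
#'
#' @param tab 5x5 confusion matrix from [confusionMatrix()] or
#'   [reconstructCounts()].
#' @param stage stage label or index; NULL returns all five.
#' @return kappa value(s) in `[-1, 1]`.
#' @export
perStageKappa <- function(tab, stage = NULL) {
  if (sum(tab) == 0) stop("perStageKappa: empty table")
  if (is.null(stage))
    return(stats::setNames(vapply(STAGES, function(s)
      perStageKappa(tab, s), numeric(1)), STAGES))
  cc <- collapse2x2(tab, stage)
  n <- sum(cc)
  po <- (cc["tp"] + cc["tn"]) / n
  pe <- ((cc["tp"] + cc["fn"]) * (cc["tp"] + cc["fp"]) +
         (cc["fp"] + cc["tn"]) * (cc["fn"] + cc["tn"])) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(0)
  unname((po - pe) / (1 - pe))
}

#' Row-percentage and overall agreement
#'
#' @param tab 5x5 confusion matrix.
#' @return list with `rowPercent` (5x5, rows normalized to 100; NaN for an
#'   empty row), `stagePercent` (diagonal of rowPercent) and `overall`
#'   (100 x trace / total).
#' @export
percentAgreement <- function(tab) {
  rt <- rowSums(tab)
  rp <- sweep(tab, 1, ifelse(rt > 0, rt, NA), "/") * 100
  list(rowPercent = rp,
       stagePercent = stats::setNames(diag(rp), STAGES),
       overall = 100 * sum(diag(tab)) / sum(tab))
}

#' Reconstruct integer counts from a printed percentage table
#'
#' Inverts the common publication format (row percentages plus row epoch
#' totals): each cell is the nearest integer to pct/100 x row total, and
#' each row is corrected to its printed total by adjusting its largest
#' cell by the rounding residual.
#'
#' @param rowPercent 5x5 matrix of row percentages (each row summing to
#'   100 within `tol`).
#' @param rowTotals length-5 integer row totals.
#' @param tol allowed deviation of a row's percentage sum from 100.
#' @return 5x5 integer matrix with `rowSums` equal to `rowTotals`.
#' @export
reconstructCounts <- function(rowPercent, rowTotals, tol = 0.5) {
  stopifnot(all(dim(rowPercent) == c(5, 5)), length(rowTotals) == 5)
  bad <- abs(rowSums(rowPercent) - 100) > tol
  if (any(bad))
    stop("reconstructCounts: row(s) ", paste(which(bad), collapse = ", "),
         " do not sum to 100 within ", tol)
  out <- matrix(0L, 5, 5, dimnames = list(manual = STAGES, auto = STAGES))
  for (i in 1:5) {
    row <- round(rowPercent[i, ] / 100 * rowTotals[i])
    resid <- rowTotals[i] - sum(row)
    # per-cell rounding contributes at most 2.5 epochs; the rest of the
    # residual comes from the printed row sum being off 100 by up to `tol`
    cap <- ceiling(abs(100 - sum(rowPercent[i, ])) / 100 * rowTotals[i]) + 3
    if (abs(resid) > cap)
      stop("reconstructCounts: rounding residual ", resid, " in row ", i,
           " exceeds ", cap, "; inputs inconsistent")
    j <- which.max(row)
    row[j] <- row[j] + resid
    out[i, ] <- as.integer(row)
  }
  out
}

#' Published pooled agreement tables
#'
#' The validation cohort's pooled manual-vs-automated cross-tabulations
#' (row percentages and row epoch totals) for the normal/mild and
#' moderate/severe sleep-disordered-breathing groups, as printed, together
#' with the printed per-stage kappas. These serve as reference inputs for
#' reconstructing counts and checking the kappa computation.
#'
#' @return list of two groups (`normalMild`, `moderateSevere`), each with
#'   `rowPercent`, `rowTotals`, `printedKappa` and `printedAutoTotals`.
#' @export
publishedAgreementTables <- function() {
  list(
    normalMild = list(
      rowPercent = matrix(c(
        79.7,  9.2,  7.7, 0.8,  2.6,
        24.7, 25.1, 38.4, 0.6, 11.2,
         6.2,  7.6, 77.7, 6.0,  2.4,
         1.8,  0.0, 13.5, 83.9, 0.9,
         4.9,  6.6, 12.4, 1.4, 74.6), 5, 5, byrow = TRUE,
        dimnames = list(manual = STAGES, auto = STAGES)),
      rowTotals = c(7342, 5436, 18167, 4234, 5462),
      printedKappa = c(W = 0.67, N1 = 0.21, N2 = 0.60, N3 = 0.76, R = 0.72),
      printedAutoTotals = c(8663, 3793, 18019, 4817, 5349)),
    moderateSevere = list(
      rowPercent = matrix(c(
        71.1, 16.9,  8.1, 0.3,  3.6,
        18.9, 30.0, 40.3, 0.4, 10.5,
         8.6, 14.1, 70.5, 4.1,  2.7,
         7.1,  0.0, 26.7, 65.0, 1.1,
         4.5, 10.8, 15.9, 1.4, 67.4), 5, 5, byrow = TRUE,
        dimnames = list(manual = STAGES, auto = STAGES)),
      rowTotals = c(9086, 6955, 10205, 1077, 2615),
      printedKappa = c(W = 0.60, N1 = 0.17, N2 = 0.48, N3 = 0.60, R = 0.58),
      printedAutoTotals = c(8851, 5349, 11430, 1204, 3104))
  )
}

#' Intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two raters' per-subject values (e.g. minutes staged
#' in one stage): ICC = (MSR - MSE) / (MSR + MSE + 2 (MSC - MSE) / n),
#' where MSR, MSC, MSE are the subject, rater and error mean squares of
#' the two-way layout.
#'
#' @param x,y paired per-subject values (length >= 3).
#' @return ICC estimate (<= 1).
#' @export
iccAbsolute <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("iccAbsolute: need >= 3 paired values")
  k <- 2
  m <- cbind(x, y)
  if (stats::var(as.numeric(m)) == 0)
    stop("iccAbsolute: zero variance in both raters")
  rowM <- rowMeans(m); colM <- colMeans(m); g <- mean(m)
  msr <- k * sum((rowM - g)^2) / (n - 1)
  msc <- n * sum((colM - g)^2) / (k - 1)
  mse <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + g)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Per-subject stage sensitivity and PPV
#'
#' Sensitivity = 100 TP / (manual positives); PPV = 100 TP / (automated
#' positives). Subjects with fewer than `minManualEpochs` manually scored
#' epochs of the stage are flagged excluded rather than reported.
#'
#' @param manual,auto [Hypnogram-class] objects of equal length.
#' @param stage stage label.
#' @param minManualEpochs inclusion floor (default 20).
#' @return list with `sensitivity`, `ppv` (NA when the automated scorer
#'   never emits the stage) and `excluded`.
#' @export
sensitivityPpv <- function(manual, auto, stage, minManualEpochs = 20) {
  m <- stages(manual) == stage; a <- stages(auto) == stage
  if (length(m) != length(a)) stop("sensitivityPpv: lengths differ")
  if (sum(m) < minManualEpochs)
    return(list(sensitivity = NA_real_, ppv = NA_real_, excluded = TRUE))
  tp <- sum(m & a)
  list(sensitivity = 100 * tp / sum(m),
       ppv = if (sum(a) == 0) NA_real_ else 100 * tp / sum(a),
       excluded = FALSE)
}

#' Sleep onset: first run of three consecutive non-wake epochs
#'
#' @param h a [Hypnogram-class].
#' @return 1-based index of the first epoch of the earliest run of at
#'   least three consecutive non-W epochs, or NA if none exists.
#' @export
sleepOnset <- function(h) {
  nonW <- stages(h) != "W"
  r <- rle(nonW)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= 3)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]] + 1)
}

#' Bin a manual-vs-automated sleep-onset difference
#'
#' The absolute onset difference in minutes is binned with boundaries at
#' 3, 10 and 20 minutes: (0, 3], (3, 10], (10, 20], (20, Inf), labelled
#' "<=3", "4-10", "11-20" and ">20".
#'
#' @param manualOnset,autoOnset epoch indices (from [sleepOnset()]).
#' @param epochLength epoch length in seconds.
#' @return the bin label, or NA if either onset is undefined.
#' @export
onsetDifferenceBin <- function(manualOnset, autoOnset, epochLength = 30) {
  if (is.na(manualOnset) || is.na(autoOnset)) return(NA_character_)
  dMin <- abs(manualOnset - autoOnset) * epochLength / 60
  if (dMin <= 3) "<=3" else if (dMin <= 10) "4-10"
  else if (dMin <= 20) "11-20" else ">20"
}

#' Sleep summary: TST, sleep efficiency and RDI
#'
#' Total sleep time is the non-wake epoch count times the epoch length;
#' sleep efficiency is TST over total recording time; RDI is respiratory
#' events per hour of sleep (NA with a flag when TST is zero).
#'
#' @param h a [Hypnogram-class].
#' @param recordingMinutes total recording time in minutes (defaults to
#'   the hypnogram span).
#' @param events a `"RespiratoryEvents"` object, or NULL.
#' @return list with `tstMinutes`, `sleepEfficiency` (percent), `rdi`,
#'   `rdiUndefined` and `onsetEpoch`.
#' @export
sleepSummary <- function(h, recordingMinutes = NULL, events = NULL) {
  epLen <- epochLength(h)
  span <- nEpochs(h) * epLen / 60
  if (is.null(recordingMinutes)) recordingMinutes <- span
  if (recordingMinutes < span - 1e-9)
    stop("sleepSummary: recording time shorter than the hypnogram span")
  tst <- sum(stages(h) != "W") * epLen / 60
  count <- if (is.null(events)) 0L else events$count
  rdi <- if (tst > 0) count / (tst / 60) else NA_real_
  list(tstMinutes = tst,
       sleepEfficiency = 100 * tst / recordingMinutes,
       rdi = rdi, rdiUndefined = tst == 0,
       onsetEpoch = sleepOnset(h))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are oriented automated minus manual; the limits are the
#' mean difference plus/minus exactly twice its standard deviation.
#'
#' @param manual,auto paired per-subject values (length >= 2).
#' @return list with `bias`, `sdDiff`, `lower`, `upper`, `mean` (pairwise
#'   means) and `diff`.
#' @export
blandAltman <- function(manual, auto) {
  if (length(manual) != length(auto) || length(manual) < 2)
    stop("blandAltman: need >= 2 pairs")
  d <- auto - manual
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sdDiff = s, lower = bias - 2 * s, upper = bias + 2 * s,
       mean = (manual + auto) / 2, diff = d)
}

#' Full epoch-by-epoch agreement report
#'
#' @param manual,auto [Hypnogram-class] objects of equal length.
#' @return an [AgreementReport-class].
#' @export
agreementReport <- function(manual, auto) {
  tab <- confusionMatrix(manual, auto)
  pa <- percentAgreement(tab)
  sens <- vapply(STAGES, function(s) {
    r <- sensitivityPpv(manual, auto, s, minManualEpochs = 0)
    r$sensitivity
  }, numeric(1))
  ppv <- vapply(STAGES, function(s) {
    r <- sensitivityPpv(manual, auto, s, minManualEpochs = 0)
    if (is.na(r$ppv)) NA_real_ else r$ppv
  }, numeric(1))
  new("AgreementReport", confusion = tab,
      kappa = perStageKappa(tab),
      rowPercent = pa$rowPercent, overallPercent = pa$overall,
      sensitivity = sens, ppv = ppv)
}
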
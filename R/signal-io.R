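## EDF (European Data Format) I/O.
## The installed stack has no R EDF package, so the small fixed-layout format
## is handled directly: 256-byte global header, 256 bytes per signal, then
## 16-bit little-endian samples grouped in data records. Only continuous EDF
## is supported; EDF+ annotation streams are ignored.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write channels to an EDF file
#'
#' Fixture-grade EDF writer: all channels must share one sampling rate and
#' length; data records are 1 s long. Physical-to-digital scaling uses a
#' symmetric physical range just covering the data, so the round-trip error
#' is at most one 16-bit quantization step of that range.
#'
#' @param channels list of [RawChannel-class] objects (equal rate and length).
#' @param path output file path.
#' @param startTime recording start (POSIXct), used only for the header.
#' @return `path`, invisibly.
#' @seealso [readEdf()]
#' @export
writeEdf <- function(channels, path,
                     startTime = as.POSIXct("2000-01-01 23:00:00", tz = "UTC")) {
  stopifnot(length(channels) >= 1)
  fs <- vapply(channels, samplingRate, numeric(1))
  ns <- vapply(channels, function(ch) length(channelSamples(ch)), numeric(1))
  if (length(unique(fs)) != 1 || length(unique(ns)) != 1)
    stop("writeEdf: all channels must share sampling rate and length")
  fs <- fs[1]
  if (abs(fs - round(fs)) > 1e-9) stop("writeEdf: sampling rate must be integer Hz")
  spr <- as.integer(round(fs))              # samples per 1-s record
  nrec <- ns[1] %/% spr
  if (nrec < 1) stop("writeEdf: less than one second of data")

  nch <- length(channels)
  digMin <- -32768L; digMax <- 32767L
  physMax <- vapply(channels, function(ch) {
    m <- max(abs(channelSamples(ch)), 1e-6)
    signif(m * 1.01, 6)
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad("X X X X", 80),
    edfPad("Startdate X X X X", 80),
    edfPad(format(startTime, "%d.%m.%y"), 8),
    edfPad(format(startTime, "%H.%M.%S"), 8),
    edfPad(256L * (1L + nch), 8),
    edfPad("", 44),
    edfPad(nrec, 8),
    edfPad("1", 8),
    edfPad(nch, 4)
  )
  field <- function(f, width) paste(vapply(seq_len(nch), function(i)
    edfPad(f(i), width), character(1)), collapse = "")
  hdr <- paste0(hdr,
    field(function(i) channelLabel(channels[[i]]), 16),
    field(function(i) "", 80),
    field(function(i) channels[[i]]@physicalUnit, 8),
    field(function(i) format(-physMax[i]), 8),
    field(function(i) format(physMax[i]), 8),
    field(function(i) digMin, 8),
    field(function(i) digMax, 8),
    field(function(i) "", 80),
    field(function(i) spr, 8),
    field(function(i) "", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # digital conversion per channel, then interleave by record
  dig <- lapply(seq_len(nch), function(i) {
    x <- channelSamples(channels[[i]])[seq_len(nrec * spr)]
    g <- (digMax - digMin) / (2 * physMax[i])
    as.integer(pmin(pmax(round((x + physMax[i]) * g + digMin), digMin), digMax))
  })
  # interleave per record: record r = ch1 block, ch2 block, ...
  stacked <- do.call(rbind, lapply(dig, matrix, nrow = spr, ncol = nrec))
  writeBin(as.integer(stacked), con, size = 2, endian = "little")
  invisible(path)
}

readEdfHeader <- function(con) {
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    trimws(raw)
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  headerBytes <- as.integer(rd(8)); reserved <- rd(44)
  nrec <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1 || is.na(nrec) || is.na(recDur))
    stop("readEdf: corrupt EDF header")
  fld <- function(width) vapply(seq_len(nch), function(i) {
    trimws(readChar(con, width, useBytes = TRUE))
  }, character(1))
  labels <- fld(16); transducer <- fld(80); unit <- fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  prefilter <- fld(80); spr <- as.integer(fld(8)); fld(32)
  if (any(is.na(physMin)) || any(is.na(spr)))
    stop("readEdf: corrupt EDF signal headers")
  list(nrec = nrec, recDur = recDur, nch = nch, labels = labels,
       unit = unit, physMin = physMin, physMax = physMax,
       digMin = digMin, digMax = digMax, spr = spr)
}

#' Read channels from an EDF file
#'
#' Digital values are converted to physical units using the header gain and
#' offset, so amplitudes are in the recorded unit (normally microvolts).
#' Label matching is case-insensitive; `aliases` maps alternative request
#' labels to labels present in the file (e.g. `c(LOC = "LEOG")`).
#'
#' @param path EDF/EDF+ file path.
#' @param channelLabels character vector of channel labels to extract; NULL
#'   reads all channels.
#' @param aliases named character vector mapping request aliases to file
#'   labels.
#' @return list of [RawChannel-class] objects, in request order.
#' @export
readEdf <- function(path, channelLabels = NULL, aliases = character()) {
  if (!file.exists(path)) stop("readEdf: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEdfHeader(con)

  want <- if (is.null(channelLabels)) h$labels else as.character(channelLabels)
  resolved <- vapply(want, function(lbl) {
    tgt <- if (lbl %in% names(aliases)) aliases[[lbl]] else lbl
    hit <- which(tolower(h$labels) == tolower(tgt))
    if (!length(hit))
      stop("readEdf: channel '", lbl, "' not found; available: ",
           paste(h$labels, collapse = ", "))
    hit[1]
  }, integer(1))

  total <- sum(h$spr) * h$nrec
  dig <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
  if (length(dig) < total) stop("readEdf: truncated data section")

  offsets <- c(0, cumsum(h$spr))
  recLen <- sum(h$spr)
  lapply(seq_along(resolved), function(k) {
    i <- resolved[k]
    idx <- as.vector(outer(offsets[i] + seq_len(h$spr[i]),
                           (seq_len(h$nrec) - 1) * recLen, `+`))
    gain <- (h$physMax[i] - h$physMin[i]) / (h$digMax[i] - h$digMin[i])
    phys <- (dig[idx] - h$digMin[i]) * gain + h$physMin[i]
    rawChannel(phys, h$spr[i] / h$recDur, h$labels[i],
               physicalUnit = if (nzchar(h$unit[i])) h$unit[i] else "uV")
  })
}

#' Derive the differential staging signal
#'
#' The staging input is the right-minus-left EOG difference: conjugate eye
#' movements (anti-phase across the two channels) add constructively while
#' common in-phase activity cancels, leaving eye movements plus residual
#' frontal EEG.
#'
#' @param left,right [RawChannel-class] objects at equal rate and length.
#' @param swap swap the roles of the two inputs (mislabeled montages).
#' @return a [RawChannel-class] labelled "REOG-LEOG".
#' @export
deriveStagingSignal <- function(left, right, swap = FALSE) {
  if (swap) { tmp <- left; left <- right; right <- tmp }
  if (samplingRate(left) != samplingRate(right))
    stop("deriveStagingSignal: sampling rates differ")
  if (length(channelSamples(left)) != length(channelSamples(right)))
    stop("deriveStagingSignal: channel lengths differ")
  rawChannel(channelSamples(right) - channelSamples(left),
             samplingRate(left), "REOG-LEOG",
             physicalUnit = left@physicalUnit)
}

#' Upsample a channel by linear interpolation
#'
#' Supports integer upsampling factors only (the operational case is
#' 128 Hz to 256 Hz). New interior samples are linear interpolations of
#' their neighbours; the final fractional position holds the last value.
#'
#' @param channel a [RawChannel-class].
#' @param targetRate target sampling rate in Hz.
#' @return a [RawChannel-class] at `targetRate`.
#' @examples
#' ch <- rawChannel(c(0, 2), 128, "x")
#' channelSamples(resampleLinear(ch, 256))  # 0 1 2 2
#' @export
resampleLinear <- function(channel, targetRate) {
  src <- samplingRate(channel)
  f <- targetRate / src
  if (f < 1 || abs(f - round(f)) > 1e-9)
    stop("resampleLinear: target rate must be an integer multiple of ",
         src, " Hz")
  f <- round(f)
  if (f == 1) return(channel)
  x <- channelSamples(channel)
  n <- length(x)
  pos <- (seq_len(n * f) - 1) / f          # 0-based source positions
  out <- stats::approx(x = 0:(n - 1), y = x, xout = pmin(pos, n - 1),
                       method = "linear")$y
  rawChannel(out, targetRate, channelLabel(channel),
             physicalUnit = channel@physicalUnit)
}

#' Segment a channel into fixed-length scoring epochs
#'
#' Epochs are consecutive and non-overlapping from the first sample (plus an
#' optional alignment offset); a trailing partial epoch is dropped and the
#' number of discarded samples recorded.
#'
#' @param channel a [RawChannel-class].
#' @param epochLength epoch length in seconds (default 30).
#' @param startOffset seconds skipped at the start for alignment with a
#'   manual hypnogram (default 0).
#' @return an [EpochedSignal-class].
#' @export
epochSignal <- function(channel, epochLength = 30, startOffset = 0) {
  fs <- samplingRate(channel)
  x <- channelSamples(channel)
  skip <- round(startOffset * fs)
  if (skip > 0) x <- x[-seq_len(min(skip, length(x)))]
  blk <- round(epochLength * fs)
  nep <- length(x) %/% blk
  if (nep < 1)
    stop("epochSignal: record shorter than one epoch (",
         length(x), " < ", blk, " samples)")
  used <- nep * blk
  new("EpochedSignal",
      samplingRate = fs, epochLength = epochLength,
      epochs = matrix(x[seq_len(used)], nrow = blk, ncol = nep),
      droppedSamples = as.integer(length(x) - used),
      label = channelLabel(channel))
}

## ---------------------------------------------------------------------------
## Hypnogram and event files

legacyStageTokens <- c("0" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "5" = "R")

#' Read / write hypnogram CSV files
#'
#' Format: a header line `epoch,stage` followed by one row per epoch with a
#' contiguous 1-based epoch index and a stage label from [STAGES]. The
#' `numeric` dialect accepts legacy numeric tokens 0/1/2/3/5 for
#' W/N1/N2/N3/R.
#'
#' @param path CSV file path.
#' @param epochLength epoch length in seconds attached to the result.
#' @param dialect `"labels"` (default) or `"numeric"`.
#' @return [readHypnogram()]: a [Hypnogram-class]; [writeHypnogram()]:
#'   `path` invisibly.
#' @export
readHypnogram <- function(path, epochLength = 30,
                          dialect = c("labels", "numeric")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("readHypnogram: no such file: ", path)
  df <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (!identical(names(df), c("epoch", "stage")))
    stop("readHypnogram: expected header 'epoch,stage'")
  if (nrow(df) < 1) stop("readHypnogram: empty hypnogram")
  if (!identical(df$epoch, seq_len(nrow(df))))
    stop("readHypnogram: epoch indices must be contiguous starting at 1")
  lab <- trimws(df$stage)
  if (dialect == "numeric") {
    bad <- which(!lab %in% names(legacyStageTokens))
    if (length(bad))
      stop("readHypnogram: unknown numeric stage token '", lab[bad[1]],
           "' at row ", bad[1])
    lab <- unname(legacyStageTokens[lab])
  }
  bad <- which(!lab %in% STAGES)
  if (length(bad))
    stop("readHypnogram: unknown stage token '", lab[bad[1]],
         "' at row ", bad[1])
  hypnogram(lab, epochLength = epochLength)
}

#' @param h a [Hypnogram-class] to write.
#' @rdname readHypnogram
#' @export
writeHypnogram <- function(h, path) {
  df <- data.frame(epoch = seq_len(nEpochs(h)), stage = stages(h))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Respiratory event lists
#'
#' Respiratory events (apneas/hypopneas) are taken as given, either as onset
#' times in seconds from record start or as a bare per-record count; they
#' feed the respiratory disturbance index (RDI = events per hour of sleep).
#'
#' @param times sorted nonnegative event onset times in seconds, or NULL.
#' @param count total event count (used when `times` is NULL).
#' @return an object of class `"RespiratoryEvents"`: a list with elements
#'   `times` (numeric or NULL) and `count`.
#' @export
respiratoryEvents <- function(times = NULL, count = NULL) {
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (any(times < 0)) stop("respiratoryEvents: negative event time")
    if (is.unsorted(times)) stop("respiratoryEvents: times must be nondecreasing")
    count <- length(times)
  } else {
    if (is.null(count)) count <- 0L
    count <- as.integer(count)
    if (count < 0) stop("respiratoryEvents: negative count")
  }
  structure(list(times = times, count = count), class = "RespiratoryEvents")
}

#' Read / write respiratory event CSV files
#'
#' A file with header `time_s` lists event onset times; a file whose single
#' line is a bare integer is read as a total event count.
#'
#' @param path CSV file path.
#' @return [readRespiratoryEvents()]: a `"RespiratoryEvents"` object.
#' @export
readRespiratoryEvents <- function(path) {
  if (!file.exists(path)) stop("readRespiratoryEvents: no such file: ", path)
  first <- readLines(path, n = 1)
  if (grepl("time_s", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    respiratoryEvents(times = df$time_s)
  } else {
    respiratoryEvents(count = as.integer(trimws(first)))
  }
}

#' @param events a `"RespiratoryEvents"` object to write.
#' @rdname readRespiratoryEvents
#' @export
writeRespiratoryEvents <- function(events, path) {
  if (!is.null(events$times)) {
    utils::write.csv(data.frame(time_s = events$times), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    writeLines(as.character(events$count), path)
  }
  invisible(path)
}
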
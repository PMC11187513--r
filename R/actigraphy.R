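# Actigraphy pipeline: raw 30 Hz tri-axial acceleration -> per-minute
# activity counts -> off-wrist masking and day exclusion -> Cole-Kripke
# minute scoring -> nightly sleep episodes.

#' Derive per-minute activity counts from raw acceleration
#'
#' Fixed pipeline: per-sample Euclidean norm of the three axes, then a
#' zero-phase 0.5-3 Hz band-pass (order-4 Butterworth equivalent,
#' applied forward and backward so sleep timing is not phase-shifted),
#' rectification with sub-threshold values zeroed, integration over
#' nonoverlapping 2-second windows, and averaging of the 30 window
#' values in each minute.
#'
#' @param accel data.frame or matrix with three acceleration columns
#'   (`ax`, `ay`, `az`, in g) sampled at `sampleRate`.
#' @param sampleRate sampling rate in Hz (30 expected); must exceed
#'   twice the upper passband edge.
#' @param start wall-clock time of the first sample (minute boundary).
#' @param band passband edges in Hz.
#' @param noiseThreshold rectified magnitudes below this level (g) are
#'   zeroed before integration.
#' @return An [EpochSeries-class] of `floor(duration / 60 s)` per-minute
#'   counts.
#' @export
accelToCounts <- function(accel, sampleRate = 30, start = "2021-09-06",
                          band = c(0.5, 3), noiseThreshold = 0.01) {
  if (is.data.frame(accel)) accel <- as.matrix(accel[, c("ax", "ay", "az")])
  stopifnot(is.matrix(accel), ncol(accel) == 3L)
  if (sampleRate <= 2 * band[2L])
    stop("sample rate ", sampleRate, " Hz cannot represent a ",
         band[2L], " Hz passband edge", call. = FALSE)
  spm <- sampleRate * 60
  nMin <- floor(nrow(accel) / spm)
  if (nMin < 1L) stop("need at least one full minute of samples", call. = FALSE)
  mag <- sqrt(rowSums(accel^2))
  bf <- signal::butter(2, band / (sampleRate / 2), type = "pass")
  filtered <- signal::filtfilt(bf, mag - mean(mag))
  rect <- abs(filtered)
  rect[rect < noiseThreshold] <- 0
  rect <- rect[seq_len(nMin * spm)]
  # integrate 2-s windows (sum * dt), then average the 30 windows/min
  wlen <- 2 * sampleRate
  wsum <- colSums(matrix(rect, nrow = wlen)) / sampleRate
  counts <- colMeans(matrix(wsum, nrow = 30))
  EpochSeries(counts, start = start, epochLength = 60L)
}

#' Flag off-wrist periods and invalid days
#'
#' Off-wrist periods (device removed for charging, showering, ...) are
#' detected as contiguous runs of sub-threshold counts of at least
#' `minRun` minutes.  Any day whose off-wrist total exceeds
#' `maxOffwrist` minutes (default 360 = 6 h) is marked invalid and is
#' excluded from downstream indicators.
#'
#' @param counts per-minute [EpochSeries-class] of activity counts.
#' @param threshold counts at or below this level are candidate
#'   off-wrist minutes (default 0: exact stillness).
#' @param minRun minimum run length in minutes for an off-wrist period.
#' @param maxOffwrist per-day off-wrist minutes above which the day is
#'   invalid (strictly greater than).
#' @param segments day segmentation; computed at local midnight if
#'   omitted.
#' @return list with `worn` (logical per minute, `FALSE` = off-wrist),
#'   `dayTable` (per-day off-wrist minutes and validity) and `series`
#'   (the input with off-wrist minutes masked invalid).
#' @export
flagOffWrist <- function(counts, threshold = 0, minRun = 30L,
                         maxOffwrist = 360L, segments = NULL) {
  stopifnot(is(counts, "EpochSeries"), epochLength(counts) == 60L)
  n <- length(counts)
  worn <- rep(TRUE, n)
  if (n == 0L)
    return(list(worn = logical(), dayTable = data.frame(), series = counts))
  runs <- .trueRuns(epochValues(counts) <= threshold)
  runs <- runs[runs$length >= minRun, , drop = FALSE]
  for (i in seq_len(nrow(runs))) worn[runs$start[i]:runs$end[i]] <- FALSE
  if (is.null(segments)) segments <- segmentDays(counts)
  off <- integer(nrow(segments))
  for (i in seq_len(nrow(segments)))
    off[i] <- sum(!worn[segments$start[i]:segments$end[i]])
  dayTable <- data.frame(date = segments$date, offwrist = off,
                         valid = segments$valid & off <= maxOffwrist)
  masked <- counts
  masked@validMask <- epochValid(counts) & worn
  list(worn = worn, dayTable = dayTable, series = masked)
}

#' Cole-Kripke minute-by-minute sleep/wake scoring
#'
#' Classifies each minute as sleep or wake from a weighted sum of the
#' activity counts in a window of preceding, current and following
#' minutes, damping the effect of isolated activity spikes.  The
#' default weights are the published 1-minute-epoch variant
#' (window -4..+2 minutes, weights 106, 54, 58, 76, 230, 74, 67, scale
#' 0.001): a minute is scored sleep when
#' \eqn{D = 0.001 (106 A_{-4} + 54 A_{-3} + 58 A_{-2} + 76 A_{-1} +
#' 230 A_0 + 74 A_{+1} + 67 A_{+2}) < 1}.
#' Weights, scale and threshold are configurable so device-specific
#' recalibrations can be expressed.
#'
#' @param counts per-minute [EpochSeries-class] of activity counts.
#' @param worn logical per-minute wear mask (from [flagOffWrist()]);
#'   off-wrist minutes are scored `invalid`.
#' @param weights window weights, centered per `offsets`.
#' @param offsets integer minute offsets matched to `weights`.
#' @param scale multiplier applied to the weighted sum.
#' @param threshold sleep criterion: sleep iff `D < threshold`.
#' @return data.frame with one row per minute: `time`, `D`, and
#'   `state` in `{"sleep","wake","invalid"}`.  Window positions past
#'   the series boundary use zero-padded neighbors.
#' @export
coleKripke <- function(counts, worn = NULL,
                       weights = c(106, 54, 58, 76, 230, 74, 67),
                       offsets = -4:2, scale = 0.001, threshold = 1) {
  stopifnot(is(counts, "EpochSeries"), epochLength(counts) == 60L,
            length(weights) == length(offsets))
  A <- epochValues(counts)
  n <- length(A)
  if (is.null(worn)) worn <- rep(TRUE, n)
  Az <- A
  Az[!worn | !epochValid(counts)] <- 0  # invalid minutes contribute no activity
  lo <- -min(offsets); hi <- max(offsets)
  pad <- c(rep(0, lo), Az, rep(0, hi))
  D <- rep(0, n)
  for (j in seq_along(weights))
    D <- D + weights[j] * pad[seq_len(n) + lo + offsets[j]]
  D <- scale * D
  state <- ifelse(D < threshold, "sleep", "wake")
  state[!worn | !epochValid(counts)] <- "invalid"
  data.frame(time = epochTimes(counts), D = D, state = state,
             stringsAsFactors = FALSE)
}

#' Nightly sleep episodes from minute sleep/wake scores
#'
#' For each night the main sleep episode is taken from the longest
#' consolidated sleep in the night window (default 18:00 to 12:00 the
#' next day): onset is the start of the first sleep run of at least
#' `minRunMin` minutes, wake is the end of the last such run, WASO is
#' the wake-scored minutes between them, and TST = (wake - onset) -
#' WASO.  Nights on days excluded for off-wrist time are skipped;
#' nights with no qualifying sleep run are returned with `NA` fields.
#'
#' @param scores minute score table from [coleKripke()].
#' @param dayTable per-day validity from [flagOffWrist()]; if supplied,
#'   a night is skipped when its evening or morning day is invalid.
#' @param nightWindow decimal hours past the date's midnight bounding
#'   the night (default `c(18, 36)` = 18:00 to 12:00 next day).
#' @param minRunMin minimum consolidated sleep run, minutes (default 60,
#'   excluding naps and transient quiescence).
#' @return data.frame of sleep episodes: `date` (the evening's date),
#'   `onset`, `wake`, `midpoint` (decimal hours past that date's
#'   midnight, so values > 24 fall after midnight: 24.35 = 00:21),
#'   `waso`, `tst` (minutes) and `source = "actigraphy"`.
#' @export
actigraphySleepEpisodes <- function(scores, dayTable = NULL,
                                    nightWindow = c(18, 36), minRunMin = 60L) {
  stopifnot(all(c("time", "state") %in% names(scores)))
  tnum <- as.numeric(scores$time)
  dates <- sort(unique(as.Date(scores$time, tz = .tz)))
  out <- list()
  for (d in as.list(dates)) {
    d0 <- as.numeric(.dateToTime(d))
    w0 <- d0 + nightWindow[1L] * 3600
    w1 <- d0 + nightWindow[2L] * 3600
    inWin <- tnum >= w0 & tnum < w1
    if (!any(inWin)) next
    if (tnum[1L] > w0 || tnum[length(tnum)] + 60 < w1) next  # incomplete night
    if (!is.null(dayTable)) {
      dv <- dayTable$valid[match(c(d, d + 1), dayTable$date)]
      if (any(!dv, na.rm = TRUE)) next
    }
    st <- scores$state[inWin]
    wt <- tnum[inWin]
    runs <- .trueRuns(st == "sleep")
    runs <- runs[runs$length >= minRunMin, , drop = FALSE]
    if (nrow(runs) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        date = d, onset = NA_real_, wake = NA_real_, midpoint = NA_real_,
        waso = NA_real_, tst = NA_real_, source = "actigraphy")
      next
    }
    onsetIdx <- runs$start[1L]
    wakeIdx <- runs$end[nrow(runs)] + 1L  # end = first minute after sleep
    onset <- (wt[onsetIdx] - d0) / 3600
    wake <- (wt[wakeIdx - 1L] + 60 - d0) / 3600
    between <- st[onsetIdx:(wakeIdx - 1L)]
    waso <- sum(between == "wake")
    tst <- (wake - onset) * 60 - waso
    out[[length(out) + 1L]] <- data.frame(
      date = d, onset = onset, wake = wake, midpoint = (onset + wake) / 2,
      waso = waso, tst = tst, source = "actigraphy")
  }
  if (!length(out))
    return(data.frame(date = as.Date(character()), onset = numeric(),
                      wake = numeric(), midpoint = numeric(), waso = numeric(),
                      tst = numeric(), source = character()))
  do.call(rbind, out)
}
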
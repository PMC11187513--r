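# Smartphone modality: event stream -> 5-minute app-counts -> near-24-h
# cycle extraction -> inactive half-cycle -> run-length sleep detection.

#' Aggregate smartphone events into 5-minute app-counts
#'
#' The app-count method: the number of interaction events per minute is
#' summed within nonoverlapping 5-minute epochs (288 epochs per day),
#' so short disengagements while the user is awake do not produce
#' spurious zero segments.  Screen on/off and app-use events count as
#' interactions; notification arrivals are passive and excluded by
#' default.
#'
#' @param log an [EventLog-class] spanning at least one day.
#' @param span optional `c(start, end)` wall-clock bounds for the
#'   series (epoch/day-aligned times or dates).  Defaults to the
#'   midnight before the first event through the midnight after the
#'   last; required when the log is empty.
#' @param includeNotifications logical; count notification arrivals as
#'   interactions (default `FALSE`).
#' @param epochSeconds epoch length (default 300 s).
#' @return An [EpochSeries-class] of integer app-counts; minutes with
#'   no events contribute 0.
#' @export
eventsToAppCounts <- function(log, span = NULL, includeNotifications = FALSE,
                              epochSeconds = 300L) {
  stopifnot(is(log, "EventLog"))
  ev <- eventRecords(log)
  kinds <- c("screen_on", "screen_off", "app_use",
             if (includeNotifications) "notification")
  ev <- ev[ev$kind %in% kinds, , drop = FALSE]
  if (is.null(span)) {
    if (nrow(ev) == 0L)
      stop("empty event log: an explicit 'span' is required", call. = FALSE)
    span <- c(.midnightOf(min(ev$timestamp)),
              .midnightOf(max(ev$timestamp)) + 86400)
  } else {
    span <- .asTime(span)
  }
  t0 <- as.numeric(span[1L]); t1 <- as.numeric(span[2L])
  if (t0 %% epochSeconds != 0)
    stop("'span' start must lie on an epoch boundary", call. = FALSE)
  nEpoch <- ceiling((t1 - t0) / epochSeconds)
  tn <- as.numeric(ev$timestamp)
  tn <- tn[tn >= t0 & tn < t0 + nEpoch * epochSeconds]
  counts <- tabulate(floor((tn - t0) / epochSeconds) + 1L, nbins = nEpoch)
  EpochSeries(counts, start = span[1L], epochLength = epochSeconds)
}

# zero-phase brick-wall band-pass keeping periods in [minPeriod, maxPeriod]
# seconds.  Circular (FFT) filtering: exactly zero-phase, and free of
# edge transients on whole-day recordings, whose circular extension is
# nearly continuous across the wrap
.fftBandpass <- function(x, dt, minPeriod, maxPeriod) {
  N <- length(x)
  k <- seq_len(N) - 1L
  freq <- pmin(k, N - k) / (N * dt)        # cycles per second, symmetric
  keep <- freq >= 1 / maxPeriod & freq <= 1 / minPeriod
  Re(fft(fft(x) * keep, inverse = TRUE)) / N
}

# dominant period (seconds) of x within [minPeriod, maxPeriod]
.dominantPeriod <- function(x, dt, minPeriod, maxPeriod) {
  N <- length(x)
  k <- seq_len(N) - 1L
  freq <- pmin(k, N - k) / (N * dt)
  keep <- which(freq >= 1 / maxPeriod & freq <= 1 / minPeriod & k <= N / 2)
  if (!length(keep)) return(NA_real_)
  mag <- Mod(fft(x))[keep]
  1 / freq[keep[which.max(mag)]]
}

#' Locate the daily inactive half-cycle of an app-count series
#'
#' Band-passes the epoch series to periods of approximately 16 to 24
#' hours (zero-phase circular FFT filter) and, for each night, centers
#' the putative sleep window on the trough of the filtered cycle: the
#' inactive half-cycle is the trough plus/minus one quarter of the
#' dominant period, clipped to 4-16 hours.
#'
#' @param appcounts an [EpochSeries-class] of app-counts covering at
#'   least 2 complete days.
#' @param periodRange period band in hours (default `c(16, 24)`).
#' @param windowRange allowed window length bounds in hours.
#' @param troughSearch decimal hours past each date's midnight within
#'   which the nightly trough is sought (default `c(18, 36)`, i.e. the
#'   night spanning that date into the next morning).
#' @return data.frame with one row per located night: `date`,
#'   `troughTime`, `start`, `end` (POSIXct window bounds), `startIdx`,
#'   `endIdx` (epoch indices, inclusive).
#' @export
extractInactiveWindows <- function(appcounts, periodRange = c(16, 24),
                                   windowRange = c(4, 16),
                                   troughSearch = c(18, 36)) {
  stopifnot(is(appcounts, "EpochSeries"))
  L <- epochLength(appcounts)
  x <- epochValues(appcounts)
  if (length(x) * L < 2 * 86400)
    stop("need at least 2 complete days of app-counts", call. = FALSE)
  if (sd(x) == 0)
    stop("no circadian cycle detectable: app-count series is constant", call. = FALSE)
  filt <- .fftBandpass(x, L, periodRange[1L] * 3600, periodRange[2L] * 3600)
  if (diff(range(filt)) < .Machine$double.eps^0.5 * max(1, mean(x)))
    stop("no circadian cycle detectable: filtered cycle is flat", call. = FALSE)
  P <- .dominantPeriod(x, L, periodRange[1L] * 3600, periodRange[2L] * 3600)
  half <- min(max(P / 2, windowRange[1L] * 3600), windowRange[2L] * 3600)
  tnum <- as.numeric(epochTimes(appcounts))
  dates <- sort(unique(as.Date(epochTimes(appcounts), tz = .tz)))
  out <- list()
  for (d in as.list(dates)) {
    d0 <- as.numeric(.dateToTime(d))
    s0 <- d0 + troughSearch[1L] * 3600
    s1 <- d0 + troughSearch[2L] * 3600
    inWin <- which(tnum >= s0 & tnum < s1)
    if (!length(inWin)) next
    if (tnum[1L] > s0 || tnum[length(tnum)] + L < s1) next  # incomplete night
    trough <- tnum[inWin[which.min(filt[inWin])]] + L / 2
    w0 <- max(trough - half / 2, tnum[1L])
    w1 <- min(trough + half / 2, tnum[length(tnum)] + L)
    i0 <- which(tnum >= w0)[1L]
    i1 <- max(which(tnum < w1))
    out[[length(out) + 1L]] <- data.frame(
      date = d,
      troughTime = as.POSIXct(trough, origin = "1970-01-01", tz = .tz),
      start = as.POSIXct(tnum[i0], origin = "1970-01-01", tz = .tz),
      end = as.POSIXct(tnum[i1] + L, origin = "1970-01-01", tz = .tz),
      startIdx = i0, endIdx = i1)
  }
  if (!length(out))
    stop("no night with complete data to locate an inactive window", call. = FALSE)
  do.call(rbind, out)
}

#' Detect a sleep episode inside an inactive window by run-length rules
#'
#' Sleep onset is the start of the first run of at least `zeroRun`
#' (default 8) consecutive zero app-count epochs inside the window;
#' wake time is the start of the first run of at least `nonzeroRun`
#' (default 6) consecutive nonzero epochs after onset, or the window
#' end if no such run occurs.  WASO is 5 minutes per nonzero epoch
#' strictly between onset and wake (isolated use bursts shorter than
#' the wake criterion); TST = (wake - onset) - WASO.
#'
#' @param appcounts the [EpochSeries-class] of app-counts.
#' @param window one row of the table from [extractInactiveWindows()].
#' @param zeroRun onset criterion: consecutive zero-count epochs.
#' @param nonzeroRun wake criterion: consecutive nonzero-count epochs.
#' @return One-row data.frame (`date`, `onset`, `wake`, `midpoint` in
#'   decimal hours past the date's midnight with values > 24 after
#'   midnight, `waso`, `tst` in minutes, `source = "app"`), or the same
#'   row with `NA` fields when no qualifying onset run exists.
#' @export
detectSleepEpisode <- function(appcounts, window, zeroRun = 8L, nonzeroRun = 6L) {
  stopifnot(is(appcounts, "EpochSeries"))
  L <- epochLength(appcounts)
  idx <- window$startIdx:window$endIdx
  b <- epochValues(appcounts)[idx] > 0
  miss <- data.frame(date = window$date, onset = NA_real_, wake = NA_real_,
                     midpoint = NA_real_, waso = NA_real_, tst = NA_real_,
                     source = "app")
  zr <- .trueRuns(!b)
  zr <- zr[zr$length >= zeroRun, , drop = FALSE]
  if (nrow(zr) == 0L) return(miss)
  onsetLoc <- zr$start[1L]
  nz <- .trueRuns(b)
  nz <- nz[nz$length >= nonzeroRun & nz$start > onsetLoc, , drop = FALSE]
  wakeLoc <- if (nrow(nz)) nz$start[1L] else length(idx) + 1L
  waso <- if (wakeLoc - onsetLoc > 1L)
    sum(b[(onsetLoc + 1L):(wakeLoc - 1L)]) * L / 60 else 0
  tnum <- as.numeric(epochTimes(appcounts))
  onsetT <- tnum[idx[1L]] + (onsetLoc - 1L) * L
  wakeT <- tnum[idx[1L]] + (wakeLoc - 1L) * L
  onset <- .decimalHours(as.POSIXct(onsetT, origin = "1970-01-01", tz = .tz),
                         window$date)
  wake <- .decimalHours(as.POSIXct(wakeT, origin = "1970-01-01", tz = .tz),
                        window$date)
  data.frame(date = window$date, onset = onset, wake = wake,
             midpoint = (onset + wake) / 2,
             waso = waso, tst = (wake - onset) * 60 - waso, source = "app")
}

#' App-count sleep pipeline: events or counts to nightly episodes
#'
#' Convenience wrapper: aggregates events to app-counts (if given an
#' [EventLog-class]), locates the nightly inactive half-cycle, and
#' applies the run-length onset/wake rules to each night.
#'
#' @param x an [EventLog-class] or an app-count [EpochSeries-class].
#' @param zeroRun,nonzeroRun run-length thresholds, see
#'   [detectSleepEpisode()].
#' @param ... passed to [extractInactiveWindows()].
#' @return data.frame of nightly sleep episodes (`source = "app"`).
#' @export
appSleepEpisodes <- function(x, zeroRun = 8L, nonzeroRun = 6L, ...) {
  appcounts <- if (is(x, "EventLog")) eventsToAppCounts(x) else x
  stopifnot(is(appcounts, "EpochSeries"))
  wins <- extractInactiveWindows(appcounts, ...)
  out <- lapply(seq_len(nrow(wins)), function(i)
    detectSleepEpisode(appcounts, wins[i, , drop = FALSE], zeroRun, nonzeroRun))
  do.call(rbind, out)
}
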
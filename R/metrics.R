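# Nonparametric circadian indicators: IS, IV, M10/L5, social jet lag,
# and the per-participant indicator row.

#' Interdaily stability from a days-by-bin matrix
#'
#' Low-level form of the IS statistic on hourly-binned data arranged as
#' a days x p matrix (`NA` = missing bin):
#' \deqn{IS = \frac{N \sum_{h=1}^{p} (\bar{x}_h - \bar{x})^2}
#'            {p \sum_{i=1}^{N} (x_i - \bar{x})^2}}
#' where \eqn{x_i} are the N non-missing binned data points,
#' \eqn{\bar{x}_h} the per-bin means across days and \eqn{\bar{x}} the
#' grand mean.  IS lies in [0, 1]; 1 for an exactly day-periodic
#' series, about 1/(number of days) for structureless noise.
#'
#' @param mat numeric matrix, days in rows, day-bins in columns.
#' @return IS value in [0, 1] (clipped there if floating error carries
#'   it out, with a warning).
#' @export
nonparIS <- function(mat) {
  stopifnot(is.matrix(mat))
  x <- mat[!is.na(mat)]
  N <- length(x)
  if (N < 2L) stop("IS needs at least 2 data points", call. = FALSE)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  if (ss == 0) stop("IS undefined for constant input", call. = FALSE)
  bm <- colMeans(mat, na.rm = TRUE)
  bm <- bm[!is.nan(bm)]
  p <- length(bm)
  val <- N * sum((bm - xbar)^2) / (p * ss)
  if (val > 1 + 1e-9 || val < -1e-9)
    warning("IS = ", format(val), " clipped into [0, 1]")
  min(max(val, 0), 1)
}

#' Intradaily variability of a binned sequence
#'
#' Low-level IV: the normalized mean squared successive difference of
#' the temporally ordered binned values,
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}
#'            {(N-1) \sum_{i=1}^{N} (x_i - \bar{x})^2}}
#' First differences are only taken between temporally adjacent
#' non-missing bins (gaps are skipped, and the difference count in the
#' denominator shrinks accordingly).  Roughly 0-2 in practice: near 0
#' for a smooth diurnal profile, about 2 for structureless noise,
#' above 2 for ultradian alternation.
#'
#' @param x numeric vector in temporal order (`NA` = missing bin).
#' @return IV value (nonnegative).
#' @export
nonparIV <- function(x) {
  ok <- !is.na(x)
  N <- sum(ok)
  if (N < 2L) stop("IV needs at least 2 valid points", call. = FALSE)
  xv <- x[ok]
  ss <- sum((xv - mean(xv))^2)
  if (ss == 0) stop("IV undefined for constant input", call. = FALSE)
  d <- diff(x)          # NA wherever either neighbor is missing
  d <- d[!is.na(d)]
  if (!length(d)) stop("IV undefined: no adjacent valid pairs", call. = FALSE)
  (sum(d^2) / length(d)) / (ss / N)
}

#' Interdaily stability of an epoch series
#'
#' Bins the series into hourly means per day (p = 24) over valid
#' complete days and applies the IS formula (see [nonparIS()]).  Both
#' modalities are binned the same way, per the convention that IS
#' operates on hourly means; app-counts may equivalently be summed to
#' hourly totals, since IS is invariant to scaling.
#'
#' @param series an [EpochSeries-class].
#' @param segments day table from [segmentDays()] (midnight anchor if
#'   omitted); only `valid` days enter.
#' @param binSeconds bin width (default hourly).
#' @return IS in [0, 1].  At least 2 complete valid days are required;
#'   constant input is an error.  Fewer than 7 days triggers a
#'   low-confidence warning.
#' @export
interdailyStability <- function(series, segments = NULL, binSeconds = 3600L) {
  if (is.null(segments)) segments <- segmentDays(series)
  mat <- .binMatrix(series, segments, binSeconds)
  if (nrow(mat) < 2L)
    stop("IS needs at least 2 complete valid days", call. = FALSE)
  if (nrow(mat) < 7L)
    warning("IS computed on fewer than 7 days; low confidence")
  nonparIS(mat)
}

#' Intradaily variability of an epoch series
#'
#' Bins the series into hourly means (per valid day), concatenates the
#' days in temporal order, and applies the normalized mean squared
#' successive difference (see [nonparIV()]).  Differences across
#' invalid days or missing bins are skipped.
#'
#' @inheritParams interdailyStability
#' @return IV value (nonnegative).
#' @export
intradailyVariability <- function(series, segments = NULL, binSeconds = 3600L) {
  if (is.null(segments)) segments <- segmentDays(series)
  if (nrow(segments[segments$valid, , drop = FALSE]) < 7L)
    warning("IV computed on fewer than 7 days; low confidence")
  p <- 86400L %/% binSeconds
  # full day grid so that a dropped (invalid) day breaks adjacency
  allDays <- seq(min(segments$date), max(segments$date), by = 1L)
  grid <- matrix(NA_real_, length(allDays), p)
  mat <- .binMatrix(series, segments, binSeconds)
  grid[match(as.Date(rownames(mat)), allDays), ] <- mat
  nonparIV(as.vector(t(grid)))
}

#' M10 and L5: most-active 10-hour and least-active 5-hour windows
#'
#' For each complete valid day, sliding windows of 10 h (M10) and 5 h
#' (L5) at epoch stride, wrapping around the day boundary, are averaged;
#' M10 is the maximum 10-h window mean and L5 the minimum 5-h window
#' mean, each with its window onset clock time.  Participant-level
#' values are the means across days (circular mean for onsets).
#'
#' @param series an [EpochSeries-class] of counts.
#' @param segments day table; computed at local midnight if omitted.
#' @param m10Hours,l5Hours window lengths in hours.
#' @return list with `m10`, `m10_onset`, `l5`, `l5_onset` (participant
#'   means), and `perDay` data.frame of the daily values.  Days where
#'   every candidate window touches a missing epoch are skipped.
#' @export
m10l5 <- function(series, segments = NULL, m10Hours = 10, l5Hours = 5) {
  if (is.null(segments)) segments <- segmentDays(series)
  segs <- segments[segments$valid, , drop = FALSE]
  if (nrow(segs) == 0L) stop("need at least 1 complete valid day", call. = FALSE)
  L <- epochLength(series)
  vals <- epochValues(series)
  ok <- epochValid(series)
  perDay <- list()
  for (i in seq_len(nrow(segs))) {
    x <- vals[segs$start[i]:segs$end[i]]
    x[!ok[segs$start[i]:segs$end[i]]] <- NA_real_
    m10 <- .circWindowStat(x, round(m10Hours * 3600 / L), max)
    l5 <- .circWindowStat(x, round(l5Hours * 3600 / L), min)
    if (is.null(m10) || is.null(l5)) next  # no window free of missing data
    perDay[[length(perDay) + 1L]] <- data.frame(
      date = segs$date[i],
      m10 = m10$value, m10_onset = (m10$start - 1L) * L / 3600,
      l5 = l5$value, l5_onset = (l5$start - 1L) * L / 3600)
  }
  if (!length(perDay)) stop("no day offers a complete M10/L5 window", call. = FALSE)
  pd <- do.call(rbind, perDay)
  list(m10 = mean(pd$m10), m10_onset = .circMeanHours(pd$m10_onset),
       l5 = mean(pd$l5), l5_onset = .circMeanHours(pd$l5_onset),
       perDay = pd)
}

# best (max/min) circular window mean of length w over x; windows
# containing NA are excluded; NULL if no window is NA-free
.circWindowStat <- function(x, w, pick) {
  n <- length(x)
  stopifnot(w >= 1L, w <= n)
  xx <- c(x, x[seq_len(w - 1L)])
  isna <- is.na(xx)
  xx0 <- ifelse(isna, 0, xx)
  cs <- c(0, cumsum(xx0))
  cn <- c(0, cumsum(isna))
  starts <- seq_len(n)
  sums <- cs[starts + w] - cs[starts]
  nas <- cn[starts + w] - cn[starts]
  means <- ifelse(nas == 0L, sums / w, NA_real_)
  if (all(is.na(means))) return(NULL)
  best <- if (identical(pick, max)) which.max(means) else which.min(means)
  list(value = means[best], start = best)
}

#' Social jet lag from nightly sleep episodes
#'
#' The absolute difference, in decimal hours, between the mean
#' midsleep on free days and on workdays.  A night is classified by
#' the day it leads into: the night starting Friday evening belongs to
#' Saturday and counts as a free night (Monday-Friday are workdays by
#' default; configurable).
#'
#' @param episodes data.frame of sleep episodes with `date` (evening
#'   date) and `midpoint` columns.
#' @param freeDays weekdays (1 = Monday ... 7 = Sunday) counted as
#'   free days; default Saturday/Sunday.
#' @param minPerClass minimum episodes required in each class.
#' @return social jet lag in hours, or `NA` (with a warning) when
#'   either class has fewer than `minPerClass` episodes.
#' @export
socialJetlag <- function(episodes, freeDays = c(6L, 7L), minPerClass = 2L) {
  ep <- episodes[!is.na(episodes$midpoint), , drop = FALSE]
  if (!nrow(ep)) {
    warning("no episodes with midpoints; social jet lag unavailable")
    return(NA_real_)
  }
  wakeDay <- as.integer(format(ep$date + 1L, "%u"))  # night leads into date+1
  free <- wakeDay %in% freeDays
  if (sum(free) < minPerClass || sum(!free) < minPerClass) {
    warning("fewer than ", minPerClass,
            " episodes in a day class; social jet lag unavailable")
    return(NA_real_)
  }
  abs(mean(ep$midpoint[free]) - mean(ep$midpoint[!free]))
}

#' Per-participant circadian indicator row
#'
#' Aggregates one participant's recording (one modality) into a single
#' indicator row: IS, IV, M10/L5 with onsets, mean sleep onset / wake /
#' midpoint (decimal hours; onset keeps the evening convention with
#' values > 24 after midnight, wake and midpoint are wrapped to clock
#' hours), mean WASO and TST in minutes, social jet lag, and the
#' number of valid days used.
#'
#' @param participantId identifier for the row.
#' @param source `"app"` or `"actigraphy"`.
#' @param episodes nightly episode table ([appSleepEpisodes()] or
#'   [actigraphySleepEpisodes()]); may have zero rows.
#' @param series the modality's count [EpochSeries-class].
#' @param segments day table; midnight anchor if omitted.  Days marked
#'   invalid (e.g. off-wrist exclusion) are dropped from IS/IV/M10/L5.
#' @param freeDays passed to [socialJetlag()].
#' @return one-row data.frame.  With fewer than 7 valid days IS/IV are
#'   still computed but `low_confidence` is `TRUE`.
#' @export
summarizeParticipant <- function(participantId, source, episodes, series,
                                 segments = NULL, freeDays = c(6L, 7L)) {
  stopifnot(source %in% c("app", "actigraphy"))
  if (is.null(segments)) segments <- segmentDays(series)
  nDays <- sum(segments$valid)
  lowConf <- nDays < 7L
  wrap <- function(x) if (is.na(x)) NA_real_ else .wrap24(x)
  is_ <- tryCatch(suppressWarnings(interdailyStability(series, segments)),
                  error = function(e) NA_real_)
  iv_ <- tryCatch(suppressWarnings(intradailyVariability(series, segments)),
                  error = function(e) NA_real_)
  ml <- tryCatch(m10l5(series, segments), error = function(e)
    list(m10 = NA_real_, m10_onset = NA_real_, l5 = NA_real_, l5_onset = NA_real_))
  hasEp <- is.data.frame(episodes) && nrow(episodes) > 0L &&
    any(!is.na(episodes$onset))
  mOnset <- if (hasEp) mean(episodes$onset, na.rm = TRUE) else NA_real_
  mWake <- if (hasEp) wrap(mean(episodes$wake, na.rm = TRUE)) else NA_real_
  mMid <- if (hasEp) wrap(mean(episodes$midpoint, na.rm = TRUE)) else NA_real_
  mWaso <- if (hasEp) mean(episodes$waso, na.rm = TRUE) else NA_real_
  mTst <- if (hasEp) mean(episodes$tst, na.rm = TRUE) else NA_real_
  sjl <- if (hasEp) suppressWarnings(socialJetlag(episodes, freeDays)) else NA_real_
  data.frame(
    participant_id = participantId, source = source,
    is = is_, iv = iv_,
    m10 = ml$m10, m10_onset = ml$m10_onset, l5 = ml$l5, l5_onset = ml$l5_onset,
    onset = mOnset, wake = mWake, midpoint = mMid,
    waso = mWaso, tst = mTst, social_jetlag = sjl,
    n_days = nDays, low_confidence = lowConf,
    stringsAsFactors = FALSE)
}
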
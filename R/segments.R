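# Day segmentation and daily-bin profiles shared by both modalities.

#' Segment an epoch series into anchor-to-anchor days
#'
#' Splits the recording into calendar days relative to a configurable
#' day anchor (default local midnight, matching the 288-epochs-per-day
#' framing of 5-minute app-counts).  Segments tile the recording
#' without overlap; partial first/last days are flagged `valid = FALSE`.
#'
#' @param series an [EpochSeries-class].
#' @param dayAnchor clock time ("HH:MM" or decimal hours) at which a
#'   day starts.
#' @return data.frame with one row per day touched by the recording:
#'   `date` (calendar date of the anchor), `start`/`end` (1-based epoch
#'   indices into `series`, inclusive), `n` (epochs) and `valid`
#'   (complete anchor-to-anchor day).
#' @export
segmentDays <- function(series, dayAnchor = "00:00") {
  stopifnot(is(series, "EpochSeries"))
  if (!length(series)) stop("cannot segment an empty series", call. = FALSE)
  L <- epochLength(series)
  perDay <- 86400L %/% L
  anchor <- .clockToSec(dayAnchor)
  secs <- as.numeric(epochTimes(series))
  day <- floor((secs - anchor) / 86400)
  idx <- split(seq_along(secs), day)
  dayIds <- as.numeric(names(idx))
  out <- data.frame(
    date = as.Date(as.POSIXct(dayIds * 86400 + anchor, origin = "1970-01-01", tz = .tz)),
    start = vapply(idx, min, 1L),
    end = vapply(idx, max, 1L),
    n = lengths(idx)
  )
  out$valid <- out$n == perDay
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

# days-by-bin matrix of bin means over valid epochs of valid segments;
# NA where a bin has no valid data
.binMatrix <- function(series, segments, binSeconds = 3600L) {
  L <- epochLength(series)
  if (binSeconds %% L != 0L)
    stop("bin width must be a multiple of the epoch length", call. = FALSE)
  perBin <- binSeconds %/% L
  p <- 86400L %/% binSeconds
  segs <- segments[segments$valid, , drop = FALSE]
  if (nrow(segs) == 0L) stop("no valid (complete) days in recording", call. = FALSE)
  vals <- epochValues(series)
  ok <- epochValid(series)
  mat <- matrix(NA_real_, nrow(segs), p)
  for (i in seq_len(nrow(segs))) {
    v <- vals[segs$start[i]:segs$end[i]]
    m <- ok[segs$start[i]:segs$end[i]]
    v[!m] <- NA_real_
    dim(v) <- c(perBin, p)
    cnt <- colSums(!is.na(v))
    s <- colSums(v, na.rm = TRUE)
    mat[i, ] <- ifelse(cnt > 0L, s / cnt, NA_real_)
  }
  rownames(mat) <- as.character(segs$date)
  mat
}

#' Average daily profile (hourly means by default)
#'
#' Computes per-bin means across valid days (hourly bins by default:
#' the mean of each clock hour over all days of the recording) and the
#' grand mean over all binned data points.  This is the profile whose
#' between-bin variance drives interdaily stability.
#'
#' @param series an [EpochSeries-class].
#' @param segments day segmentation from [segmentDays()]; computed at
#'   local midnight if omitted.  Only `valid` (complete) days are used.
#' @param binSeconds bin width in seconds (default 3600 = hourly,
#'   `p = 24` bins per day).
#' @return An [HourlyProfile-class].  Bins with no valid epochs on any
#'   day are `NA`; it is an error only if every bin is empty.
#' @export
hourlyProfile <- function(series, segments = NULL, binSeconds = 3600L) {
  if (is.null(segments)) segments <- segmentDays(series)
  mat <- .binMatrix(series, segments, binSeconds)
  pts <- mat[!is.na(mat)]
  if (!length(pts)) stop("all daily bins are empty", call. = FALSE)
  bm <- colMeans(mat, na.rm = TRUE)
  bm[is.nan(bm)] <- NA_real_
  new("HourlyProfile",
      binMeans = bm,
      grandMean = mean(pts),
      nDays = nrow(mat),
      N = length(pts),
      p = ncol(mat),
      binSeconds = as.integer(binSeconds))
}
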
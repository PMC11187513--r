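#' EpochSeries: regularly sampled nonnegative counts with a missing-mask
#'
#' The shared container for both modalities: per-minute actigraphy
#' counts (`epochLength = 60`) and 5-minute smartphone app-counts
#' (`epochLength = 300`, 288 epochs per complete day).  Missing epochs
#' are represented through `validMask = FALSE`, never by zero — a zero
#' is a meaningful observation (no movement / no interaction).
#'
#' @slot start POSIXct; wall-clock time of the first epoch boundary.
#' @slot epochLength integer; epoch length in seconds.  Must divide
#'   86400 so that days tile into whole epochs (288 five-minute or 1440
#'   one-minute epochs per day).
#' @slot values numeric; one nonnegative value per epoch.
#' @slot validMask logical; `TRUE` where the epoch carries data.
#'
#' @aliases EpochSeries
#' @exportClass EpochSeries
setClass("EpochSeries",
  representation(
    start = "POSIXct",
    epochLength = "integer",
    values = "numeric",
    validMask = "logical"
  )
)

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (length(object@start) != 1L || is.na(object@start))
    msg <- c(msg, "'start' must be a single non-NA POSIXct")
  L <- object@epochLength
  if (length(L) != 1L || is.na(L) || L <= 0L)
    msg <- c(msg, "'epochLength' must be a single positive integer")
  else if (86400L %% L != 0L)
    msg <- c(msg, "'epochLength' must divide 86400 seconds")
  if (length(object@values) != length(object@validMask))
    msg <- c(msg, "'values' and 'validMask' must have equal length")
  vals <- object@values[object@validMask]
  if (length(vals) && any(vals < 0, na.rm = TRUE))
    msg <- c(msg, "valid 'values' must be nonnegative")
  if (length(L) == 1L && !is.na(L) && L > 0L &&
      as.numeric(object@start) %% L != 0)
    msg <- c(msg, "'start' must lie on an epoch boundary")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSeries
#'
#' @param values numeric vector of nonnegative epoch values.
#' @param start epoch-boundary start time (POSIXct or parseable string;
#'   timezone-naive local wall clock).
#' @param epochLength epoch length in seconds; must divide 86400.
#'   60 for actigraphy counts, 300 for app-counts.
#' @param validMask logical vector marking epochs that carry data;
#'   defaults to all `TRUE` (NAs in `values` are marked invalid).
#' @return An [EpochSeries-class] object.
#' @examples
#' es <- EpochSeries(rpois(288, 3), start = "2021-09-06", epochLength = 300)
#' es
#' @export
EpochSeries <- function(values, start, epochLength, validMask = NULL) {
  values <- as.numeric(values)
  if (is.null(validMask)) validMask <- !is.na(values)
  start <- .asTime(start)
  new("EpochSeries",
      start = start,
      epochLength = as.integer(epochLength),
      values = values,
      validMask = as.logical(validMask))
}

#' @describeIn EpochSeries-class number of epochs
#' @param x an `EpochSeries`
#' @export
setMethod("length", "EpochSeries", function(x) length(x@values))

#' Accessors for EpochSeries slots
#'
#' `epochValues()`, `epochValid()`, `epochStart()` and `epochLength()`
#' read the corresponding slots; `epochTimes()` returns the wall-clock
#' start time of every epoch.
#'
#' @param x an [EpochSeries-class]
#' @return the slot contents (or POSIXct vector for `epochTimes`).
#' @name EpochSeries-accessors
NULL

#' @rdname EpochSeries-accessors
#' @export
epochValues <- function(x) x@values

#' @rdname EpochSeries-accessors
#' @export
epochValid <- function(x) x@validMask

#' @rdname EpochSeries-accessors
#' @export
epochStart <- function(x) x@start

#' @rdname EpochSeries-accessors
#' @export
epochLength <- function(x) x@epochLength

#' @rdname EpochSeries-accessors
#' @export
epochTimes <- function(x) {
  x@start + (seq_along(x@values) - 1L) * as.numeric(x@epochLength)
}

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@values)
  cat(sprintf("EpochSeries: %d epochs of %ds (%.2f days) starting %s\n",
              n, object@epochLength, n * object@epochLength / 86400,
              format(object@start, "%Y-%m-%d %H:%M")))
  cat(sprintf("  valid: %d/%d epochs; value range [%g, %g]\n",
              sum(object@validMask), n,
              suppressWarnings(min(object@values[object@validMask])),
              suppressWarnings(max(object@values[object@validMask]))))
})

.EVENT_KINDS <- c("screen_on", "screen_off", "notification", "app_use")

#' EventLog: timestamped smartphone interaction records
#'
#' Ordered records of the three collected smartphone variables: screen
#' on/off events, notification arrivals, and app-use events (the app in
#' the foreground).  Timestamps are timezone-naive local wall clock.
#'
#' @slot events data.frame with columns `timestamp` (POSIXct,
#'   nondecreasing), `kind` (one of `"screen_on"`, `"screen_off"`,
#'   `"notification"`, `"app_use"`) and `app_id` (character; `NA`
#'   except for app_use rows).
#'
#' @aliases EventLog
#' @exportClass EventLog
setClass("EventLog", representation(events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("timestamp", "kind", "app_id")
  if (!all(need %in% names(ev)))
    msg <- c(msg, paste("'events' must have columns", paste(need, collapse = ", ")))
  else {
    if (!inherits(ev$timestamp, "POSIXct"))
      msg <- c(msg, "'timestamp' must be POSIXct")
    else if (is.unsorted(as.numeric(ev$timestamp)))
      msg <- c(msg, "timestamps must be nondecreasing")
    bad <- setdiff(unique(ev$kind), .EVENT_KINDS)
    if (length(bad))
      msg <- c(msg, paste0("unknown event kind(s): ", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventLog
#'
#' Rows are sorted by timestamp; `app_id` is retained for app_use rows.
#'
#' @param timestamp POSIXct (or parseable) event times.
#' @param kind character; one of `"screen_on"`, `"screen_off"`,
#'   `"notification"`, `"app_use"`.
#' @param app_id optional opaque app label (used for app_use rows).
#' @return An [EventLog-class] object.
#' @export
EventLog <- function(timestamp, kind, app_id = NA_character_) {
  ev <- data.frame(
    timestamp = .asTime(timestamp),
    kind = as.character(kind),
    app_id = rep_len(as.character(app_id), length(timestamp)),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventLog", events = ev)
}

#' @describeIn EventLog-class number of events
#' @param x an `EventLog`
#' @export
setMethod("length", "EventLog", function(x) nrow(x@events))

#' Event records of an EventLog
#' @param x an [EventLog-class]
#' @return data.frame with columns timestamp, kind, app_id.
#' @export
eventRecords <- function(x) x@events

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat(sprintf("EventLog: %d events", nrow(ev)))
  if (nrow(ev)) {
    cat(sprintf(" spanning %s .. %s\n",
                format(min(ev$timestamp), "%Y-%m-%d %H:%M"),
                format(max(ev$timestamp), "%Y-%m-%d %H:%M")))
    print(table(factor(ev$kind, levels = .EVENT_KINDS)))
  } else cat("\n")
})

#' HourlyProfile: per-day-bin mean activity profile
#'
#' The average daily profile underlying interdaily stability: `p` bin
#' means across the day (hourly bins by default, so `p = 24`), the
#' grand mean, and the bookkeeping counts `N` (total binned data
#' points) and `nDays` (valid days contributing).
#'
#' @slot binMeans numeric; mean per day-bin across days (`NA` where a
#'   bin has no valid data).
#' @slot grandMean numeric; mean of all binned data points.
#' @slot nDays integer; number of valid days.
#' @slot N integer; total number of non-missing binned data points.
#' @slot p integer; bins per day.
#' @slot binSeconds integer; bin width in seconds.
#'
#' @aliases HourlyProfile
#' @exportClass HourlyProfile
setClass("HourlyProfile",
  representation(
    binMeans = "numeric",
    grandMean = "numeric",
    nDays = "integer",
    N = "integer",
    p = "integer",
    binSeconds = "integer"
  )
)

setValidity("HourlyProfile", function(object) {
  msg <- character()
  if (length(object@binMeans) != object@p)
    msg <- c(msg, "'binMeans' must have length p")
  if (object@N > object@p * object@nDays)
    msg <- c(msg, "N cannot exceed p * nDays")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HourlyProfile", function(object) {
  cat(sprintf("HourlyProfile: %d bins/day (%ds), %d days, N = %d points\n",
              object@p, object@binSeconds, object@nDays, object@N))
  cat(sprintf("  grand mean %.4g; bin means [%.4g, %.4g]\n",
              object@grandMean,
              suppressWarnings(min(object@binMeans, na.rm = TRUE)),
              suppressWarnings(max(object@binMeans, na.rm = TRUE))))
})

#' @rdname HourlyProfile-class
#' @param x an `HourlyProfile`
#' @export
profileBinMeans <- function(x) x@binMeans

#' @rdname HourlyProfile-class
#' @export
profileGrandMean <- function(x) x@grandMean

#' @rdname HourlyProfile-class
#' @export
profileN <- function(x) x@N
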
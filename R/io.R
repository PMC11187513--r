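# Delimited-text readers/writers shared by both modalities.

.parseTimestamps <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = .tz)
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = .tz))
  }
  out
}

#' Read a smartphone event log from delimited text
#'
#' Expected columns: `timestamp` (ISO-8601, e.g. `2021-09-06T22:41:00`),
#' `kind` (one of screen_on, screen_off, notification, app_use) and an
#' optional `app_id`.  Rows are sorted by timestamp on read.
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter (default comma).
#' @return An [EventLog-class].
#' @details Unparseable timestamps or kinds outside the closed set are
#'   hard errors naming the offending data row; an empty file is an
#'   error.  Whether app-use rows come from foreground polling or
#'   launch events is irrelevant here: both arrive as generic
#'   `app_use` records.
#' @export
readEventLog <- function(path, delim = ",") {
  df <- tryCatch(
    read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character", quote = "\"", comment.char = ""),
    error = function(e) stop("cannot read event log '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("event log '", path, "' contains no data rows", call. = FALSE)
  need <- c("timestamp", "kind")
  if (!all(need %in% names(df)))
    stop("event log must have columns 'timestamp' and 'kind'", call. = FALSE)
  ts <- suppressWarnings(.parseTimestamps(df$timestamp))
  if (anyNA(ts))
    stop("unparseable timestamp in event log at data row(s) ",
         paste(head(which(is.na(ts)), 5L), collapse = ", "), call. = FALSE)
  badKind <- !(df$kind %in% .EVENT_KINDS)
  if (any(badKind))
    stop("unknown event kind '", df$kind[which(badKind)[1L]],
         "' at data row ", which(badKind)[1L], call. = FALSE)
  app <- if ("app_id" %in% names(df)) df$app_id else NA_character_
  EventLog(ts, df$kind, app)
}

#' Write / read an epoch series as delimited text
#'
#' Columns: `timestamp`, `value`, `valid`.  The epoch length is
#' inferred on read from the timestamp spacing, which must be regular.
#'
#' @param series an [EpochSeries-class].
#' @param path file path.
#' @param delim field delimiter.
#' @return `readEpochSeries` returns an [EpochSeries-class];
#'   `writeEpochSeries` invisibly returns `path`.
#' @export
writeEpochSeries <- function(series, path, delim = ",") {
  df <- data.frame(
    timestamp = format(epochTimes(series), "%Y-%m-%dT%H:%M:%S"),
    value = format(epochValues(series), digits = 15, trim = TRUE, scientific = FALSE),
    valid = epochValid(series)
  )
  write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEpochSeries
#' @export
readEpochSeries <- function(path, delim = ",") {
  df <- read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("epoch series '", path, "' contains no data rows", call. = FALSE)
  ts <- .parseTimestamps(df$timestamp)
  if (anyNA(ts)) stop("unparseable timestamp in epoch series at data row(s) ",
                      paste(head(which(is.na(ts)), 5L), collapse = ", "), call. = FALSE)
  dt <- unique(diff(as.numeric(ts)))
  if (length(dt) != 1L)
    stop("epoch series timestamps are not regularly spaced", call. = FALSE)
  EpochSeries(as.numeric(df$value), start = ts[1L], epochLength = dt,
              validMask = as.logical(df$valid))
}

#' Write / read a participant indicator table
#'
#' One header plus one row per participant-by-modality.  Numeric values
#' survive a write/read round trip to at least 6 significant digits.
#'
#' @param rows data.frame of indicator rows (as produced by
#'   [summarizeParticipant()]).
#' @param path file path.
#' @param delim field delimiter.
#' @return `readIndicators` returns the data.frame;
#'   `writeIndicators` invisibly returns `path`.
#' @export
writeIndicators <- function(rows, path, delim = ",") {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- format(out[[j]], digits = 15, trim = TRUE, scientific = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIndicators
#' @export
readIndicators <- function(path, delim = ",") {
  read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE)
}
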
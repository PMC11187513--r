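# Internal time helpers.  All timestamps are timezone-naive local
# wall-clock, represented as POSIXct in UTC so that arithmetic never
# crosses a daylight-saving transition.

.tz <- "UTC"

.asTime <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = .tz))
  as.POSIXct(x, tz = .tz)
}

# "18:30" or "18:30:00" -> seconds past midnight
.clockToSec <- function(x) {
  if (is.numeric(x)) return(x * 3600)
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (any(is.na(parts)) || length(parts) < 1L || length(parts) > 3L)
    stop("cannot parse clock time '", x, "'", call. = FALSE)
  sum(parts * c(3600, 60, 1)[seq_along(parts)])
}

# midnight (00:00 local) of the calendar date containing t
.midnightOf <- function(t) {
  t <- .asTime(t)
  as.POSIXct(floor(as.numeric(t) / 86400) * 86400, origin = "1970-01-01", tz = .tz)
}

.dateToTime <- function(d) as.POSIXct(paste(as.character(d), "00:00:00"), tz = .tz)

# decimal hours of t past the midnight starting calendar date `date`
.decimalHours <- function(t, date) {
  as.numeric(difftime(.asTime(t), .dateToTime(date), units = "hours"))
}

.wrap24 <- function(h) ((h %% 24) + 24) %% 24

# circular mean of clock hours, result in [0, 24)
.circMeanHours <- function(h) {
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_real_)
  ang <- h / 24 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  .wrap24(m / (2 * pi) * 24)
}

# run-length scan: start indices and lengths of maximal TRUE runs
.trueRuns <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], length = r$lengths[keep], end = ends[keep])
}

# evaluate expr with a local RNG seed, restoring global state after
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
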
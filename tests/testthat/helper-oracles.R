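# Independent brute-force oracles used to cross-check the vectorized
# implementations.  These deliberately use naive loops and literal
# formula transcriptions, sharing no code with the package internals.

# naive run-length sleep scanner on a binary epoch vector (TRUE = nonzero
# app-count): returns 1-based onset/wake epoch positions and WASO epochs
naiveRunScan <- function(b, zeroRun = 8L, nonzeroRun = 6L) {
  n <- length(b)
  onset <- NA_integer_
  for (i in seq_len(n - zeroRun + 1L)) {
    if (all(!b[i:(i + zeroRun - 1L)])) { onset <- i; break }
  }
  if (is.na(onset)) return(NULL)
  wake <- n + 1L
  i <- onset + 1L
  while (i <= n - nonzeroRun + 1L) {
    if (all(b[i:(i + nonzeroRun - 1L)])) { wake <- i; break }
    i <- i + 1L
  }
  wasoEpochs <- 0L
  if (wake - onset > 1L)
    for (j in (onset + 1L):(wake - 1L)) if (b[j]) wasoEpochs <- wasoEpochs + 1L
  list(onset = onset, wake = wake, waso = wasoEpochs)
}

# exhaustive circular-window enumeration for M10/L5 on one day of values
bruteWindow <- function(x, w, pick = max) {
  n <- length(x)
  best <- NULL
  for (s in seq_len(n)) {
    idx <- ((s - 1L) + seq_len(w) - 1L) %% n + 1L
    vals <- x[idx]
    if (anyNA(vals)) next
    m <- mean(vals)
    if (is.null(best) || identical(pick, max) && m > best$value ||
        identical(pick, min) && m < best$value)
      best <- list(value = m, start = s)
  }
  best
}

# literal transcription of the IS formula with explicit loops
directIS <- function(mat) {
  xs <- c()
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat)))
    if (!is.na(mat[i, j])) xs <- c(xs, mat[i, j])
  N <- length(xs); xbar <- sum(xs) / N
  num <- 0; p <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]; col <- col[!is.na(col)]
    if (!length(col)) next
    p <- p + 1
    num <- num + (sum(col) / length(col) - xbar)^2
  }
  den <- 0
  for (x in xs) den <- den + (x - xbar)^2
  N * num / (p * den)
}

# literal IV with explicit loops (no gaps)
directIV <- function(x) {
  N <- length(x); xbar <- sum(x) / N
  num <- 0
  for (i in 2:N) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  for (i in 1:N) den <- den + (x[i] - xbar)^2
  N * num / ((N - 1) * den)
}

# EpochSeries holding given per-day bin values (one epoch per bin)
daySeries <- function(dayValues, binSeconds = 3600L, start = "2021-09-06") {
  EpochSeries(as.vector(t(dayValues)), start = start, epochLength = binSeconds)
}

# one-day square-wave app-count series repeated nDays times:
# `level` during [onHour, offHour), else zero, 5-minute epochs
squareWaveDays <- function(nDays, onHour = 8, offHour = 24, level = 10,
                           start = "2021-09-06") {
  hrs <- (seq_len(288) - 1L) * 5 / 60
  day <- ifelse(hrs >= onHour & hrs < offHour, level, 0)
  EpochSeries(rep(day, nDays), start = start, epochLength = 300L)
}
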
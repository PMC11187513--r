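# Paired synthetic recordings (smartphone events + actigraphy counts)
# with known ground-truth circadian architecture.

#' Simulation configuration for paired synthetic recordings
#'
#' Defines the ground-truth circadian architecture shared by both
#' emitted modalities.  Defaults emulate a 4-week free-living
#' recording of an adult with a near-24-hour rest-activity cycle:
#' sleep onset around 23:30 with half-hour day-to-day phase jitter,
#' about 7.5 h of sleep, roughly one brief night awakening, daytime
#' phone use at a moderate event rate and negligible use while asleep.
#'
#' @param nDays number of nights (>= 7).
#' @param startDate first calendar date of the recording (default a
#'   Monday so a 28-day run holds 8 free-day nights).
#' @param meanOnset mean sleep onset, decimal hours past midnight of
#'   the night's date (23.5 = 23:30).
#' @param onsetJitterSd SD of day-to-day onset jitter, hours.  This is
#'   the ground-truth (in)stability dial: larger jitter lowers IS.
#' @param sleepDurationMean,sleepDurationSd sleep duration, hours
#'   (must satisfy 0 < mean < 16).
#' @param wasoEventsPerNight Poisson rate of night awakenings.
#' @param wasoEventDuration duration of each awakening, minutes.
#' @param dayUsageRate smartphone interaction events per waking hour.
#' @param nightUsageRate events per sleeping hour (~0).
#' @param notificationRate passive notification arrivals per hour
#'   (around the clock; excluded from app-counts by default).
#' @param weekendPhaseDelay hours added to onset on nights leading
#'   into free days (Saturday/Sunday).
#' @param activityDayLevel,activityNightLevel mean actigraphy count
#'   scale awake / asleep (Gamma-distributed per minute).
#' @param gammaShape shape of the per-minute Gamma counts.
#' @param offWristBlocks optional list of `list(day =, startHour =,
#'   durationMin =)` blocks zeroed in the actigraphy trace (default
#'   none), to exercise off-wrist exclusion.
#' @param naps optional list of `list(day =, startHour =,
#'   durationMin =)` daytime naps (default none).
#' @param seed integer; fixes all randomness of [simulatePair()].
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(nDays = 28L, startDate = "2021-09-06",
                      meanOnset = 23.5, onsetJitterSd = 0.5,
                      sleepDurationMean = 7.5, sleepDurationSd = 0.5,
                      wasoEventsPerNight = 1, wasoEventDuration = 10,
                      dayUsageRate = 30, nightUsageRate = 0,
                      notificationRate = 1,
                      weekendPhaseDelay = 0,
                      activityDayLevel = 200, activityNightLevel = 0.5,
                      gammaShape = 2,
                      offWristBlocks = list(), naps = list(),
                      seed = NULL) {
  cfg <- list(nDays = as.integer(nDays), startDate = as.Date(startDate),
              meanOnset = meanOnset, onsetJitterSd = onsetJitterSd,
              sleepDurationMean = sleepDurationMean,
              sleepDurationSd = sleepDurationSd,
              wasoEventsPerNight = wasoEventsPerNight,
              wasoEventDuration = wasoEventDuration,
              dayUsageRate = dayUsageRate, nightUsageRate = nightUsageRate,
              notificationRate = notificationRate,
              weekendPhaseDelay = weekendPhaseDelay,
              activityDayLevel = activityDayLevel,
              activityNightLevel = activityNightLevel,
              gammaShape = gammaShape,
              offWristBlocks = offWristBlocks, naps = naps, seed = seed)
  rates <- c(cfg$wasoEventsPerNight, cfg$dayUsageRate, cfg$nightUsageRate,
             cfg$notificationRate, cfg$activityDayLevel, cfg$activityNightLevel)
  if (any(rates < 0)) stop("rates and levels must be nonnegative", call. = FALSE)
  if (cfg$sleepDurationMean <= 0 || cfg$sleepDurationMean >= 16)
    stop("sleepDurationMean must lie in (0, 16) hours", call. = FALSE)
  if (cfg$nDays < 7L) stop("nDays must be at least 7", call. = FALSE)
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate one participant's paired recording
#'
#' Draws a nightly schedule (onset jitter, duration, awakenings,
#' optional weekend phase delay) and emits both modalities from it:
#' smartphone interaction events as an inhomogeneous Poisson process
#' (day rate while awake, night rate while asleep, day rate again
#' during awakenings) and per-minute actigraphy counts as Gamma draws
#' around the awake/asleep activity levels.  The recording spans
#' `nDays + 1` calendar days so every night window is complete.
#'
#' @param config a [simConfig()].
#' @param seed overrides `config$seed` when given.
#' @return list with `events` ([EventLog-class]), `actigraphy`
#'   (per-minute [EpochSeries-class]), `appcounts` (5-minute
#'   [EpochSeries-class] consistent with `events`), and `truth`
#'   (data.frame of per-night ground truth: `date`, `onset`, `wake`
#'   in decimal hours past the night's midnight, `waso`, `tst` in
#'   minutes, `free`).
#' @export
simulatePair <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(seed)) seed <- config$seed
  .withSeed(seed, {
    nD <- config$nDays
    dates <- config$startDate + seq_len(nD) - 1L
    free <- as.integer(format(dates + 1L, "%u")) %in% c(6L, 7L)
    onset <- config$meanOnset + ifelse(free, config$weekendPhaseDelay, 0) +
      rnorm(nD, 0, config$onsetJitterSd)
    dur <- pmin(pmax(rnorm(nD, config$sleepDurationMean,
                           config$sleepDurationSd), 2), 15.9)
    if (any(dur >= 24)) stop("infeasible schedule: duration >= 24 h", call. = FALSE)
    wake <- onset + dur
    if (any(wake >= 42))
      stop("infeasible schedule: wake after next night window", call. = FALSE)

    totDays <- nD + 1L
    nMin <- totDays * 1440L
    t0 <- .dateToTime(config$startDate)
    asleep <- rep(FALSE, nMin)
    wasoFlag <- rep(FALSE, nMin)
    wasoMin <- numeric(nD)
    for (d in seq_len(nD)) {
      a <- floor((d - 1L) * 1440 + onset[d] * 60)
      b <- floor((d - 1L) * 1440 + wake[d] * 60)
      a <- max(a, 0L); b <- min(b, nMin)
      if (b > a) asleep[(a + 1L):b] <- TRUE
      k <- rpois(1L, config$wasoEventsPerNight)
      if (k > 0L && dur[d] * 60 > config$wasoEventDuration + 60) {
        st <- runif(k, onset[d] + 0.5,
                    wake[d] - 0.5 - config$wasoEventDuration / 60)
        for (s in st) {
          i0 <- floor((d - 1L) * 1440 + s * 60)
          i1 <- min(i0 + config$wasoEventDuration, nMin)
          wasoFlag[(i0 + 1L):i1] <- TRUE
        }
      }
      nightIdx <- (a + 1L):b
      wasoMin[d] <- sum(wasoFlag[nightIdx])
    }
    for (np in config$naps) {
      i0 <- floor((np$day - 1L) * 1440 + np$startHour * 60)
      i1 <- min(i0 + np$durationMin, nMin)
      asleep[(i0 + 1L):i1] <- TRUE
    }
    awake <- !asleep | wasoFlag

    # smartphone events
    lam <- ifelse(awake, config$dayUsageRate, config$nightUsageRate) / 60
    perMin <- rpois(nMin, lam)
    mins <- rep.int(seq_len(nMin) - 1L, perMin)
    evTimes <- t0 + mins * 60 + runif(length(mins)) * 60
    kinds <- sample(c("screen_on", "screen_off", "app_use"),
                    length(mins), replace = TRUE, prob = c(0.3, 0.3, 0.4))
    apps <- ifelse(kinds == "app_use",
                   sprintf("app%02d", sample.int(20L, length(mins), replace = TRUE)),
                   NA_character_)
    nNotif <- rpois(1L, config$notificationRate * nMin / 60)
    if (nNotif > 0L) {
      evTimes <- c(evTimes, t0 + runif(nNotif) * nMin * 60)
      kinds <- c(kinds, rep("notification", nNotif))
      apps <- c(apps, rep(NA_character_, nNotif))
    }
    events <- EventLog(evTimes, kinds, apps)

    # actigraphy counts (per-minute Gamma around awake/asleep levels)
    lev <- ifelse(awake, config$activityDayLevel, config$activityNightLevel)
    acount <- rgamma(nMin, shape = config$gammaShape,
                     scale = lev / config$gammaShape)
    for (bl in config$offWristBlocks) {
      i0 <- floor((bl$day - 1L) * 1440 + bl$startHour * 60)
      i1 <- min(i0 + bl$durationMin, nMin)
      acount[(i0 + 1L):i1] <- 0
    }
    acti <- EpochSeries(acount, start = t0, epochLength = 60L)

    # app-counts from the same per-minute event counts
    app <- EpochSeries(colSums(matrix(perMin, nrow = 5L)),
                       start = t0, epochLength = 300L)

    truth <- data.frame(date = dates, onset = onset, wake = wake,
                        waso = wasoMin, tst = dur * 60 - wasoMin, free = free)
    list(events = events, actigraphy = acti, appcounts = app, truth = truth)
  })
}

#' Simulate a labeled cohort of paired recordings
#'
#' Independent participants per group, each generated by
#' [simulatePair()] with a per-participant seed derived from `seed`.
#'
#' @param groupConfigs named list of [simConfig()] objects (>= 2
#'   groups).
#' @param nPerGroup participants per group (>= 2).
#' @param seed base seed for per-participant seeds.
#' @return list with `recordings` (list of [simulatePair()] outputs)
#'   and `labels` (data.frame `participant`, `group`).
#' @export
simulateCohort <- function(groupConfigs, nPerGroup, seed = 1L) {
  if (length(groupConfigs) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (nPerGroup < 2L) stop("nPerGroup must be at least 2", call. = FALSE)
  if (is.null(names(groupConfigs)) || any(names(groupConfigs) == ""))
    stop("groupConfigs must be a named list", call. = FALSE)
  recs <- list(); labels <- list(); pid <- 0L
  for (g in names(groupConfigs)) {
    for (i in seq_len(nPerGroup)) {
      pid <- pid + 1L
      recs[[pid]] <- simulatePair(groupConfigs[[g]],
                                  seed = (seed * 10007L + pid) %% .Machine$integer.max)
      labels[[pid]] <- data.frame(participant = sprintf("P%03d", pid), group = g)
    }
  }
  list(recordings = recs, labels = do.call(rbind, labels))
}
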
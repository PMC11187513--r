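# Acceleration-to-count pipeline, off-wrist exclusion, Cole-Kripke
# scoring, nightly episode extraction.

sineAccel <- function(freqHz, amp, minutes, fs = 30) {
  t <- seq_len(minutes * 60 * fs) / fs
  cbind(ax = amp * sin(2 * pi * freqHz * t), ay = 0, az = 0)
}

test_that("zero acceleration yields all-zero minute counts", {
  counts <- accelToCounts(matrix(0, 10 * 60 * 30, 3), noiseThreshold = 0)
  expect_equal(length(counts), 10L)
  expect_equal(epochValues(counts), rep(0, 10))
})

test_that("count derivation is linear pre-threshold and monotone in amplitude", {
  c1 <- epochValues(accelToCounts(sineAccel(1, 0.1, 5), noiseThreshold = 0))
  c2 <- epochValues(accelToCounts(sineAccel(1, 0.2, 5), noiseThreshold = 0))
  expect_equal(c2 / c1, rep(2, 5), tolerance = 1e-9)
  c3 <- epochValues(accelToCounts(sineAccel(1, 0.15, 5), noiseThreshold = 0))
  expect_true(all(c3 >= c1))
})

test_that("out-of-band motion is strongly attenuated", {
  inBand <- epochValues(accelToCounts(sineAccel(1, 0.2, 5), noiseThreshold = 0))
  outBand <- epochValues(accelToCounts(sineAccel(10, 0.2, 5), noiseThreshold = 0))
  expect_lt(mean(outBand), 0.05 * mean(inBand))
})

test_that("too-low sample rates are rejected", {
  expect_error(accelToCounts(matrix(0, 600, 3), sampleRate = 5),
               "cannot represent")
})

test_that("off-wrist runs and the 6-hour day rule are applied", {
  day <- rep(50, 1440)
  mk <- function(zeroMin, at = 60) {
    x <- day; x[at + seq_len(zeroMin)] <- 0
    EpochSeries(x, start = "2021-09-06", epochLength = 60L)
  }
  expect_false(flagOffWrist(mk(7 * 60))$dayTable$valid)   # > 6 h discarded
  expect_true(flagOffWrist(mk(5 * 60))$dayTable$valid)
  expect_equal(flagOffWrist(mk(7 * 60))$dayTable$offwrist, 420L)
  # runs shorter than the minimum are kept as worn minutes
  expect_true(all(flagOffWrist(mk(20))$worn))
})

test_that("off-wrist detection matches a brute-force run scan", {
  set.seed(31)
  for (rep in 1:20) {
    x <- ifelse(runif(1440) < 0.3, 0, rpois(1440, 40))
    s <- EpochSeries(x, start = "2021-09-06", epochLength = 60L)
    worn <- flagOffWrist(s, threshold = 0, minRun = 30L)$worn
    # oracle: scan every minute for membership in a >= 30-min zero run
    oracle <- rep(TRUE, 1440)
    i <- 1L
    while (i <= 1440L) {
      if (x[i] == 0) {
        j <- i
        while (j < 1440L && x[j + 1L] == 0) j <- j + 1L
        if (j - i + 1L >= 30L) oracle[i:j] <- FALSE
        i <- j + 1L
      } else i <- i + 1L
    }
    expect_equal(worn, oracle)
  }
  # an active trace with no sub-threshold run has zero off-wrist minutes
  act <- EpochSeries(rpois(1440, 40) + 1, start = "2021-09-06", epochLength = 60L)
  expect_true(all(flagOffWrist(act)$worn))
})

test_that("Cole-Kripke scores sleep for stillness, wake around spikes", {
  quiet <- EpochSeries(rep(0, 60), start = "2021-09-06", epochLength = 60L)
  sc <- coleKripke(quiet)
  expect_true(all(sc$state == "sleep"))
  expect_equal(sc$D, rep(0, 60))

  x <- rep(0, 60); x[30] <- 1e6
  sc2 <- coleKripke(EpochSeries(x, start = "2021-09-06", epochLength = 60L))
  # the spike enters the -4..+2 window of minutes 28..34
  expect_equal(which(sc2$state == "wake"), 28:34)
})

test_that("constant-count sleep threshold agrees with the closed form", {
  w <- c(106, 54, 58, 76, 230, 74, 67)
  cstar <- 1 / (0.001 * sum(w))               # D = 1 exactly at this count
  for (c0 in c(0.9, 0.999, 1.001, 1.1) * cstar) {
    s <- EpochSeries(rep(c0, 120), start = "2021-09-06", epochLength = 60L)
    interior <- 10:110                        # away from zero-padded edges
    states <- coleKripke(s)$state[interior]
    expect_true(all(states == if (c0 < cstar) "sleep" else "wake"))
  }
})

scoresFromStates <- function(states, start = "2021-09-06") {
  n <- length(states)
  data.frame(time = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 60,
             D = ifelse(states == "sleep", 0, 2), state = states,
             stringsAsFactors = FALSE)
}

test_that("episode fields follow their definitions on constructed nights", {
  states <- rep("wake", 2 * 1440)
  sleepIdx <- (23 * 60 + 1):(31 * 60)         # 23:00 day 1 .. 07:00 day 2
  states[sleepIdx] <- "sleep"
  ep <- actigraphySleepEpisodes(scoresFromStates(states))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$onset, 23)
  expect_equal(ep$wake, 31)
  expect_equal(ep$tst, 480)
  expect_equal(ep$waso, 0)
  expect_equal(ep$midpoint, 27)               # 03:00

  states2 <- states
  states2[(27 * 60 + 1):(27 * 60 + 20)] <- "wake"   # 03:00-03:20 awake
  ep2 <- actigraphySleepEpisodes(scoresFromStates(states2))
  expect_equal(ep2$waso, 20)
  expect_equal(ep2$tst, 460)
  expect_equal(ep2$onset, 23)
  expect_equal(ep2$wake, 31)
})

test_that("TST + WASO equals the sleep-period span on simulated nights", {
  sim <- simulatePair(simConfig(nDays = 7, seed = 13))
  fw <- flagOffWrist(sim$actigraphy)
  ep <- actigraphySleepEpisodes(coleKripke(sim$actigraphy, fw$worn), fw$dayTable)
  ok <- !is.na(ep$onset)
  expect_gt(sum(ok), 0)
  expect_equal(ep$tst[ok] + ep$waso[ok], (ep$wake[ok] - ep$onset[ok]) * 60)
})

test_that("scoring is shift-equivariant in time", {
  states <- rep("wake", 2 * 1440)
  states[(23 * 60 + 1):(31 * 60)] <- "sleep"
  base <- actigraphySleepEpisodes(scoresFromStates(states))
  k <- 47L                                     # shift the night later by k minutes
  shifted <- c(rep("wake", k), states[seq_len(length(states) - k)])
  ep <- actigraphySleepEpisodes(scoresFromStates(shifted))
  expect_equal(ep$onset, base$onset + k / 60)
  expect_equal(ep$wake, base$wake + k / 60)
  expect_equal(ep$midpoint, base$midpoint + k / 60)
})

test_that("a programmed awakening is recovered in WASO within 2 minutes", {
  cfg <- simConfig(nDays = 7, onsetJitterSd = 0, wasoEventsPerNight = 0,
                   nightUsageRate = 0, seed = 77)
  sim <- simulatePair(cfg)
  # inject a deterministic 20-min awakening at 02:30 of night 3
  acount <- epochValues(sim$actigraphy)
  i0 <- 2L * 1440L + floor(26.5 * 60)
  acount[(i0 + 1L):(i0 + 20L)] <- 300
  acti <- EpochSeries(acount, start = epochStart(sim$actigraphy), epochLength = 60L)
  ep <- actigraphySleepEpisodes(coleKripke(acti))
  night3 <- ep[ep$date == sim$truth$date[3], ]
  # the -4..+2 weight window can extend the scored awakening by up to
  # 2 min before and 4 min after the true block, never shorten it
  expect_gte(night3$waso, 20)
  expect_lte(night3$waso, 26)
  others <- ep[ep$date != sim$truth$date[3] & !is.na(ep$waso), ]
  expect_true(all(others$waso <= 4))
})

test_that("excluding an off-wrist day leaves other days' episodes unchanged", {
  cfg <- simConfig(nDays = 10, seed = 19)
  base <- simulatePair(cfg)
  cfgOff <- simConfig(nDays = 10, seed = 19,
                      offWristBlocks = list(list(day = 4, startHour = 9,
                                                 durationMin = 7 * 60)))
  off <- simulatePair(cfgOff)
  fwB <- flagOffWrist(base$actigraphy); fwO <- flagOffWrist(off$actigraphy)
  expect_true(all(fwB$dayTable$valid))
  expect_false(fwO$dayTable$valid[4])
  epB <- actigraphySleepEpisodes(coleKripke(base$actigraphy, fwB$worn), fwB$dayTable)
  epO <- actigraphySleepEpisodes(coleKripke(off$actigraphy, fwO$worn), fwO$dayTable)
  shared <- setdiff(intersect(epB$date, epO$date),
                    c(off$truth$date[3], off$truth$date[4]))
  expect_gt(length(shared), 5)
  expect_equal(epB[epB$date %in% shared, ], epO[epO$date %in% shared, ],
               ignore_attr = TRUE)
})
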
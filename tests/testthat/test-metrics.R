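# Nonparametric indicators: IS, IV, M10/L5, social jet lag, summary row.

test_that("IS reproduces hand-computable matrices and the direct formula", {
  expect_equal(nonparIS(rbind(c(1, 3), c(1, 3))), 1)   # identical days
  expect_equal(nonparIS(rbind(c(1, 3), c(3, 1))), 0)   # profile = grand mean
  set.seed(51)
  for (i in 1:25) {
    mat <- matrix(runif(sample(3:8, 1) * 24), ncol = 24)
    if (i %% 3 == 0) mat[sample(length(mat), 5)] <- NA
    expect_equal(nonparIS(mat), directIS(mat), tolerance = 1e-12)
  }
})

test_that("IS is 1 for day-periodic series and affine-invariant", {
  set.seed(52)
  day <- runif(24, 0, 10)
  mat <- matrix(rep(day, each = 9), nrow = 9)
  expect_equal(nonparIS(mat), 1, tolerance = 1e-12)
  noisy <- mat + matrix(rnorm(length(mat)), nrow = 9)
  expect_equal(nonparIS(2.7 * noisy + 13), nonparIS(noisy), tolerance = 1e-10)
  # periodic through the EpochSeries route as well
  s <- EpochSeries(rep(day, 9), start = "2021-09-06", epochLength = 3600L)
  expect_equal(interdailyStability(s), 1, tolerance = 1e-12)
})

test_that("IS of iid noise concentrates near 1/days", {
  set.seed(53)
  d <- 7
  vals <- replicate(500, nonparIS(matrix(runif(d * 24), nrow = d)))
  expect_lt(abs(mean(vals) - 1 / d), 0.01)
})

test_that("constant input makes IS and IV undefined", {
  expect_error(nonparIS(matrix(5, 3, 24)), "constant")
  expect_error(nonparIV(rep(2, 50)), "constant")
  s <- EpochSeries(rep(2, 2 * 288), start = "2021-09-06", epochLength = 300L)
  expect_error(suppressWarnings(interdailyStability(s)), "constant")
})

test_that("IV reproduces hand values, the direct formula, and known regimes", {
  expect_equal(nonparIV(c(1, 3, 1, 3)), 4)             # sum diff^2 12, dev^2 4
  set.seed(54)
  for (i in 1:25) {
    x <- rnorm(sample(20:200, 1))
    expect_equal(nonparIV(x), directIV(x), tolerance = 1e-12)
  }
  # hourly sinusoid over 7 days: IV ~ 2(1 - cos(2 pi / 24)), well below 0.5
  h <- 0:(7 * 24 - 1)
  sine <- 5 + 3 * sin(2 * pi * h / 24)
  closedForm <- 2 * (1 - cos(2 * pi / 24))
  expect_lt(nonparIV(sine), 0.5)
  expect_equal(nonparIV(sine), closedForm, tolerance = 0.05)
  # iid noise: IV about 2
  iid <- replicate(500, nonparIV(rnorm(168)))
  expect_lt(abs(mean(iid) - 2), 0.1)
  # monotone ramp: far below the iid value
  expect_lt(nonparIV(seq(0, 10, length.out = 168)), 0.1)
  # affine invariance
  x <- rnorm(100)
  expect_equal(nonparIV(3 * x - 7), nonparIV(x), tolerance = 1e-10)
})

test_that("IV skips first differences across gaps", {
  x <- c(1, 5, NA, 2, 4)
  # usable diffs: (5-1), (4-2); N = 4 valid points
  xv <- c(1, 5, 2, 4)
  expected <- (sum(c(4, 2)^2) / 2) / (sum((xv - mean(xv))^2) / 4)
  expect_equal(nonparIV(x), expected)
})

test_that("series-level IV matches the binned vector route", {
  sim <- simulatePair(simConfig(nDays = 7, seed = 55))
  seg <- segmentDays(sim$appcounts)
  mat <- t(vapply(which(seg$valid), function(i) {
    v <- epochValues(sim$appcounts)[seg$start[i]:seg$end[i]]
    colMeans(matrix(v, nrow = 12))
  }, numeric(24)))
  expect_equal(suppressWarnings(intradailyVariability(sim$appcounts)),
               nonparIV(as.vector(t(mat))), tolerance = 1e-12)
})

test_that("M10/L5 match definitions on rectangles and exhaustive search", {
  hrs <- (seq_len(288) - 1L) * 5 / 60
  day <- ifelse(hrs >= 8 & hrs < 18, 100, 0)
  s <- EpochSeries(rep(day, 2), start = "2021-09-06", epochLength = 300L)
  r <- m10l5(s)
  expect_equal(r$m10, 100)
  expect_equal(r$m10_onset, 8)
  expect_equal(r$l5, 0)

  const <- EpochSeries(rep(7, 288), start = "2021-09-06", epochLength = 300L)
  rc <- m10l5(const)
  expect_equal(rc$m10, 7)
  expect_equal(rc$l5, 7)

  set.seed(56)
  for (i in 1:20) {
    x <- rpois(288, 5) * runif(288)
    if (i %% 4 == 0) x[30:44] <- NA   # one contiguous missing block
    sx <- EpochSeries(x, start = "2021-09-06", epochLength = 300L,
                      validMask = !is.na(x))
    rx <- m10l5(sx)
    o10 <- bruteWindow(x, 120, max)
    o5 <- bruteWindow(x, 60, min)
    expect_equal(rx$m10, o10$value, tolerance = 1e-12)
    expect_equal(rx$m10_onset, (o10$start - 1) * 5 / 60)
    expect_equal(rx$l5, o5$value, tolerance = 1e-12)
    expect_equal(rx$l5_onset, (o5$start - 1) * 5 / 60)
  }
})

mkEpisodes <- function(midpoints, dates) {
  data.frame(date = dates, onset = midpoints - 4, wake = midpoints + 4,
             midpoint = midpoints, waso = 0, tst = 480, source = "app")
}

test_that("social jet lag is the work/free midsleep difference", {
  dates <- as.Date("2021-09-06") + 0:13       # two full Mon-Sun weeks
  wakeDay <- as.integer(format(dates + 1, "%u"))
  mids <- ifelse(wakeDay %in% 6:7, 29, 27)    # 05:00 vs 03:00
  expect_equal(socialJetlag(mkEpisodes(mids, dates)), 2)
  expect_equal(socialJetlag(mkEpisodes(rep(27.5, 14), dates)), 0)
  onlyWork <- mkEpisodes(mids, dates)[!(wakeDay %in% 6:7), ]
  expect_warning(sjl <- socialJetlag(onlyWork), "unavailable")
  expect_true(is.na(sjl))
})

test_that("participant summary rows carry all indicator fields", {
  s <- EpochSeries(rep(c(rep(0, 96), rep(6, 192)), 28),
                   start = "2021-09-06", epochLength = 300L)
  seg <- segmentDays(s)
  ep <- appSleepEpisodes(s)
  row <- summarizeParticipant("P9", "app", ep, s, seg)
  expect_equal(row$n_days, 28L)
  expect_false(row$low_confidence)
  expect_equal(row$is, 1)
  expect_equal(row$source, "app")

  # empty episode list: sleep fields missing, row still emitted
  row0 <- summarizeParticipant("P0", "app", ep[0, ], s, seg)
  expect_equal(nrow(row0), 1L)
  expect_true(is.na(row0$onset) && is.na(row0$tst) && is.na(row0$social_jetlag))
  expect_equal(row0$is, 1)                     # series indicators unaffected

  short <- EpochSeries(rep(c(rep(0, 96), rep(6, 192)), 3),
                       start = "2021-09-06", epochLength = 300L)
  rowS <- summarizeParticipant("P1", "app", ep[0, ], short)
  expect_true(rowS$low_confidence)
})

test_that("increasing onset jitter decreases IS in the simulator", {
  jitters <- c(0.2, 1.0, 2.5)
  meanIS <- vapply(jitters, function(j) {
    mean(vapply(1:8, function(r) {
      sim <- simulatePair(simConfig(nDays = 14, onsetJitterSd = j),
                          seed = 6000 + r)
      suppressWarnings(interdailyStability(sim$appcounts))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanIS) < 0))
})
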
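---
title: "Measuring rest-activity rhythms from smartphone interactions and actigraphy"
author: "rhythmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rest-activity rhythms from smartphone interactions and actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmkit)
```

## The measurement problem

Wrist actigraphy is the established field method for rest-activity
rhythm assessment: an accelerometer on the non-dominant wrist is
reduced to per-minute activity counts, and quiescence is read as rest.
It captures physical movement only.  Human-smartphone interaction
streams — screen on/off events, notification arrivals, and the app in
the foreground — offer a complementary window: they register cognitive
and social engagement that involves almost no movement, and they are
collected passively at no extra burden.  `rhythmkit` implements both
measurement chains down to a common set of sleep and circadian
indicators so that the two modalities can be compared night by night
and participant by participant on identical definitions.

Both chains share one container, the `EpochSeries`: regularly sampled
nonnegative values with a validity mask.  Missing epochs are always
expressed through the mask, never as zeros — a zero count is a
meaningful observation (no movement, no interaction).  All timestamps
are timezone-naive local wall clock; daylight-saving transitions are
out of scope (the recording setting this design targets has no DST).
Days are segmented at local midnight by default; the anchor is
configurable because nothing in the measurement model fixes it.

## The app-count method

Smartphone use is bursty: an engaged user still leaves gaps of a few
minutes.  Counting interaction events per minute and then summing the
minute counts within nonoverlapping 5-minute epochs (288 epochs per
day) absorbs those short disengagements while preserving the diurnal
envelope.  `eventsToAppCounts()` counts screen on/off and app-use
events; notification arrivals are excluded by default because they are
initiated by the network, not the user — a config flag includes them
for sensitivity analyses, since the collection layer records them
either way.

Sleep detection then proceeds in two stages.

**Stage 1 — locate the inactive half-cycle.**  The epoch series is
band-passed to periods of roughly 16-24 hours and the putative sleep
window for each night is centered on the trough of the filtered cycle:
trough ± one quarter of the dominant period, clipped to 4-16 h.  The
filter is a zero-phase circular FFT band-pass.  We chose circular
filtering over reflection padding deliberately: reflection flips the
phase of odd-symmetric components, which in testing dragged the
filtered trough tens of minutes per day away from the true inactivity
center, whereas on whole-day recordings the circular extension is
nearly continuous across the wrap and exactly zero-phase.  (An IIR
band-pass at these normalized frequencies — the band edges sit three
orders of magnitude below the epoch Nyquist — is numerically fragile;
a spectral mask is exact.)  A constant series has no cycle and is a
hard error rather than a fabricated window.

**Stage 2 — run-length rules inside the window.**  Sleep onset is the
start of the first run of at least 8 consecutive zero-count epochs
(40 min of no interaction); wake is the start of the first run of at
least 6 consecutive nonzero epochs (30 min of sustained interaction)
after onset, or the window end if none occurs.  Both thresholds are
configurable: falling asleep mid-use (the classic streaming-video
failure mode) biases onset late, and a stricter zero-run length is the
documented mitigation.  We date each episode by the evening it begins
and report times in decimal hours past that date's midnight, letting
values run past 24 (24.35 = 00:21) so that averaging onsets across
nights never wraps.

WASO needs a convention of its own: isolated use bursts inside the
sleep window that are too short to qualify as wake (runs of fewer than
6 nonzero epochs) are counted as wake-after-sleep-onset at 5 minutes
per nonzero epoch, and TST = (wake − onset) − WASO.  This is the only
reading under which the run-length rules, a reported WASO, and the TST
identity are simultaneously consistent.  It also implies app-measured
WASO is an upper-bound-style estimate — a single notification check
costs 5 minutes — which matches the empirical pattern that app WASO
runs longer than actigraphy WASO.

## The actigraphy chain

`accelToCounts()` fixes the count-derivation pipeline: per-sample
Euclidean norm of the three axes, zero-phase 0.5-3 Hz band-pass,
rectification with sub-noise-threshold values zeroed, integration over
nonoverlapping 2-second windows, and averaging of the 30 window values
per minute.  The band-pass is realized as order-2 Butterworth sections
run forward and backward (`signal::filtfilt`), i.e. an order-4
zero-phase response; any filter within about 1 dB of that response
in-band is an acceptable substitute.  Zero-phase matters here because
a causal filter would delay every sleep onset estimate by the filter's
group delay.

Off-wrist handling: contiguous runs of sub-threshold counts of at
least 30 minutes (configurable — devices differ in noise floor) are
flagged as not worn, and any day with more than 6 hours off-wrist is
excluded outright.  Exclusion is day-local by construction: removing a
day cannot change the indicators computed from other days.

Sleep/wake scoring uses the Cole-Kripke weighted moving sum in its
published 1-minute-epoch form: minute *t* is scored sleep when

D = 0.001 (106 A(t−4) + 54 A(t−3) + 58 A(t−2) + 76 A(t−1) + 230 A(t) + 74 A(t+1) + 67 A(t+2)) < 1.

Weights, scale and criterion are exposed as configuration because
device-specific recalibrations of this family are common; the defaults
are the standard values above.  Boundary minutes use zero-padded
neighbors.  One consequence worth knowing: the −4..+2 window smears
any true awakening by up to 2 minutes before and 4 after, so scored
WASO systematically exceeds ground truth by 0-6 minutes per awakening.
The nightly episode is assembled from the longest consolidated sleep
in an 18:00-to-noon night window, with a 60-minute minimum run so naps
and brief quiescence do not masquerade as the main sleep period.

## Nonparametric circadian indicators

Interdaily stability (IS) is the variance-ratio statistic on
hourly-binned data:

IS = ( N · Σₕ (x̄ₕ − x̄)² ) / ( p · Σᵢ (xᵢ − x̄)² )

with xᵢ the N hourly data points, x̄ₕ the p = 24 hourly means across
days and x̄ the grand mean.  IS is 1 for an exactly day-periodic
series, near 1/d for d days of structureless noise, and invariant to
affine rescaling — so it compares meaningfully across modalities with
different count scales.  Values outside [0, 1] can only arise from
floating error and are clipped with a warning; a constant series makes
IS undefined and is an error.  Both modalities are binned to hourly
means before the ratio (app-counts may equivalently be summed 12
epochs to the hour; scaling cancels).  IS is computed on raw, not
band-filtered, counts by default: filtering would leak the extraction
step's assumptions into the regularity statistic.

Intradaily variability (IV) quantifies fragmentation as the normalized
mean squared successive difference,

IV = ( N · Σᵢ (xᵢ − xᵢ₋₁)² ) / ( (N−1) · Σᵢ (xᵢ − x̄)² ),

on the same hourly bins in temporal order.  With missing bins, only
differences between temporally adjacent valid bins are used and the
difference count replaces N−1.  A smooth sinusoidal day profile gives
IV ≈ 2(1 − cos(2π/24)) ≈ 0.07; independent noise gives IV ≈ 2;
hour-to-hour alternation can exceed 2.  Relative amplitude is
deliberately not implemented: app-counts are near-zero through every
night, which pins the least-active-5-hour level and empties the
statistic of information.  Cosinor fitting is likewise deliberately
absent — the populations of interest have disrupted rhythms, and
app-counts are not the continuous, near-sinusoidal signal cosinor
assumes.

M10 and L5 (most-active 10-h and least-active 5-h window means, with
window onset clock times) are computed per day by sliding windows at
epoch stride with wrap-around at the day boundary, then averaged
across days (circular mean for onsets).  Social jet lag is the
absolute difference between mean midsleep on free nights and work
nights; a night is classified by the day it leads into (Friday night
is a free night), Monday-Friday are workdays by default, and both are
configurable because cohort-specific schedules vary.

IS and IV are reported from any recording of at least 2 complete days
but flagged low-confidence below 7 days, the accepted minimum for a
stable estimate.

## The synthetic generator

`simulatePair()` emits a paired recording from one ground-truth
schedule so every pipeline stage has a parameter-recovery test without
participant data.  Nightly sleep onset is Gaussian around a mean onset
with configurable day-to-day jitter — jitter is the ground-truth
stability dial — plus an optional phase delay on nights leading into
free days; duration is Gaussian; awakenings are Poisson events of
fixed duration.  Smartphone events follow an inhomogeneous Poisson
process (a daytime rate while awake, near-zero while asleep, daytime
rate again during awakenings); actigraphy counts are per-minute Gamma
draws around awake/asleep activity levels.  Families were chosen for
simplicity; the parameters, not the distributions, are the test
surface.

Defaults describe a realistic 4-week free-living recording: 28 nights
starting on a Monday, onset 23:30 ± 0.5 h, 7.5 ± 0.5 h of sleep, one
10-minute awakening per night, 30 interaction events per waking hour,
1 notification per hour, Gamma(shape 2) activity at level 200 awake
versus 0.5 asleep.  The onset and duration centers sit in the range
reported for adult cohorts of this kind; the event rate corresponds to
roughly 500 interactions per day, typical of moderate smartphone use
and high enough that the 6-epoch wake rule triggers promptly after
true wake.  Optional off-wrist blocks and naps (default off) exercise
the exclusion logic.

What the generator does *not* emulate: weekday structure in daytime
usage, seasonal or photoperiod effects, gradual phase drift,
device-specific count noise spectra, or correlated dropout between
modalities.  Passing recovery tests therefore demonstrate that the
algorithms invert the generative model they were built for — onset
MAE, WASO and TST biases on real recordings will be larger, and the
app/actigraphy comparison on real data retains systematic differences
(cognitive activity without movement) that no shared-schedule
simulation can produce.

## Power and sample-size layer

The design calculator treats the omnibus one-way fixed-effects ANOVA:
power is the upper tail of the noncentral F distribution with
df = (k−1, N−k) and noncentrality λ = f²·N, the standard fixed-effects
convention.  `requiredBalancedN()` searches total N upward in
multiples of k with at least 2 per group — balanced allocation is the
only reading under which the three published adiposity sample sizes
(9, 15 and 9 at f = 2.59, 1.16, 1.90; k = 3, α = .05, power 0.90) are
mutually consistent, and it matches the equal-allocation default of
common power software.  `cohensF()` implements the definitional
effect-size formula (n-weighted between-group SD over pooled
within-group SD); it makes no claim to reproduce any particular
published effect-size table, whose derivation from F statistics is
not always recoverable.  `standardizedRegression()` is thin reporting
plumbing: OLS on z-scored response and predictors with standardized
coefficients, SEs, p values and adjusted R².

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(nDays = 28, weekendPhaseDelay = 2, seed = 11)
sim <- simulatePair(cfg)

ep  <- appSleepEpisodes(sim$appcounts)
row <- summarizeParticipant("P01", "app", ep, sim$appcounts)
row[, c("is", "iv", "onset", "midpoint", "tst", "social_jetlag")]

fw  <- flagOffWrist(sim$actigraphy)
aep <- actigraphySleepEpisodes(coleKripke(sim$actigraphy, fw$worn),
                               fw$dayTable)
```

## Numerical conventions and test scales

Epoch alignment floors timestamps into half-open intervals
[t, t + epoch); epoch lengths must divide 86400 s so days tile.
Ties in the night-window search resolve to the earliest index.  The
package's validation suite runs entirely on generated data at fixed
seeds: run-length detection is checked against a naive scanner on
1,000 random epoch sequences, M10/L5 against exhaustive window
enumeration, IS/IV against literal-formula transcriptions and
hand-computed vectors, and parameter recovery on cohorts of 20
simulated participants per group over 28 days with 100 cohort
replicates — sizes chosen to keep Monte-Carlo error well below the
tolerances being asserted while the full suite completes in a few
minutes on one CPU.

## Known limitations

App-derived onset is biased late for users who fall asleep mid-use;
the zero-run threshold is the exposed mitigation.  App WASO counts any
isolated nighttime interaction burst at full epoch cost and so
overestimates wakefulness relative to actigraphy.  Cole-Kripke scoring
smears awakenings by its weight window (above).  The 16-24 h
extraction assumes at least 2 complete days and one dominant
near-circadian component; shift-work schedules with split sleep will
defeat the single-trough-per-night model.  None of the sleep measures
here are validated against polysomnography or melatonin phase within
this package; they are rest-activity proxies.
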
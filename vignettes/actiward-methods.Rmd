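---
title: "Methods: passive-movement correction and circadian analysis of ward actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive-movement correction and circadian analysis of ward actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actiward)
```

## Why correct at all

In care-dependent patients (e.g. disorders of consciousness), a wrist
actigraph records two superimposed processes: the patient's own motor
activity, and passive movements imposed by staff and visitors. The second
process is scheduled — nursing rounds, therapies, and visiting hours recur at
the same clock times every day — so it masquerades as a circadian rhythm of
the patient. Every index that rewards day-to-day regularity (interdaily
stability, the 24-h periodogram peak, day-night contrast) is biased upward
by uncorrected passive movements, while the fragmentation index IV is also
inflated because quiet baseline is interrupted by bursts of handling.
actiward's pipeline removes logged care episodes, imputes the gaps, and
quantifies rhythmicity on both the uncorrected and the corrected data so the
bias itself can be measured.

## Data model

An `ActivitySeries` is a regular grid of nonnegative activity values
(arbitrary device units). Epoch timestamps label the epoch start and cover
`[t, t + epochSeconds)`; all timestamps are timezone-naive local clock time,
because ward schedules and the day/night windows are defined on the wall
clock. Sub-minute recordings are reduced with `downsampleToMinutes()`, which
sums raw values per minute (count-like semantics; a mean aggregator is
available) and drops a trailing partial minute. How a device converts raw
accelerometry to epoch counts is out of scope — the package takes epoch
counts as given.

The `EventLog` mirrors a bedside tablet: interval events (visit, nursing,
therapy, wheelchair, mobilization outside, device off, CRS-R assessment)
with start/end, and point events (medication, nutrition, lights, eye state)
that never trigger removal.

## Correction stage

1. **Padding.** Each removable event is expanded by a type-specific pad:
   5 min before and after nursing, 10 min around visits and wheelchair use
   (defaults of `defaultPaddingPolicy()`). The pads exist because staff press
   the buttons late (or early); the remaining types default to no padding but
   are configurable.
2. **Snapping and merging.** Padded windows are clipped to the recording,
   snapped *outward* to epoch boundaries (conservative removal), and
   overlapping or abutting windows are merged into maximal disjoint removal
   intervals (via `IRanges`), each remembering all source event types.
3. **Imputation.** For an interval of `n` epochs, the first `ceiling(n/2)`
   epochs get the median of up to 10 min of activity immediately *preceding*
   the interval, the rest the median of up to 10 min immediately *following*
   it. Two deliberate choices: (a) with odd `n` the preceding median gets the
   extra epoch — a deterministic tie-break; (b) context windows are taken
   relative to the *merged, padded* interval and skip epochs inside other
   removal intervals, because minutes adjacent to a logged event are exactly
   the ones the padding distrusts. At a recording boundary the available
   side's median fills the whole interval; if neither side has context the
   series is uncorrectable.
4. **Accounting and exclusion.** `removedFraction()` and
   `removedFractionReport()` expose how much was removed, per event type. No
   published numeric exclusion threshold exists for recordings that lose
   almost everything to cleaning, so the package errors above a removed
   fraction of 0.9 and warns above 0.5 (both configurable) — the error
   mirrors the situation of a patient excluded because hardly any activity
   remained after cleaning.

Correcting an already corrected series with the same log is the identity;
on a constant series correction changes nothing; imputed values always lie
within the range of the context they were computed from. The human visual
screening step that followed the automatic correction in the original
workflow is represented only by a hook: `correctSeries(extraIntervals = ...)`
accepts additional removal windows.

## Circadian metrics

**IS/IV.** With the series averaged into clock-aligned bins (`binMinutes`,
default 60 — the classical choice; `binMinutes = 1` works on the raw minute
grid), `p` bins per day, `N` bins total, bin values `x_i`, clock-time means
`xbar_h`:

$$IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{N \sum_{i \ge 2} (x_i - x_{i-1})^2}{(N-1) \sum_i (x_i - \bar x)^2}.$$

IS is 1 for any exactly 24-h-periodic signal over whole days and has
expectation ~`1/n_days` for white noise (~1/7 for a week); IV is ~0 for a
smooth sinusoid (`2(1 - cos(2*pi/24))` ≈ 0.068 for an hourly-binned 24-h
sine), ~2 for white noise, and 4 for a strictly alternating sequence. Both
are invariant to positive affine rescaling. Zero-variance series yield `NA`
with a warning — undefined results propagate explicitly, never as silent
zeros.

**Lomb-Scargle.** The classical normalized periodogram (power
`P(omega)` normalized by twice the sample variance, with the usual phase
constant `tau`) is computed in C++ over a frequency grid of density
`ofac = 100` relative to the natural spacing 1/span. Per-frequency
false-alarm probabilities use `FAP = 1 - (1 - exp(-P))^M` with
`M = n_grid / ofac`, the conventional effective number of independent
frequencies for an `ofac`-times oversampled grid; the 200-seed white-noise
suite in the tests confirms the resulting family-wise false-positive rate at
`alpha = 0.001` stays at or below 0.02. `lombScargle()` defaults to the full
grid (span down to twice the epoch), but `summarizeSeries()` scans 3-48 h by
default: peak selection anchors at 24 h, so periods far outside the
circadian band carry no information for classification, and restricting the
grid keeps `M` tied to the band actually searched (it also makes a 7-day
minute-resolution scan take seconds rather than minutes). Missing epochs are
simply dropped — the estimator accepts uneven sampling.

**Peak extraction and classification.** Among strict local maxima of the
power (plateau runs are represented by the element nearest the target, a
documented tie-break) with `FAP < alpha`, `extractCircadianPeak()` selects
the one closest to 24 h, reports its deviation `|period - 24|`, and
classifies the series circadian when the deviation is strictly below 1 h —
a deviation of exactly 1.0 h is therefore *not* circadian. If no significant
peak exists the period is undefined and the series is non-circadian.

**Day/night.** Mean activity over epochs whose start falls in
[07:00, 21:00) vs the complement, matching the ward's lights-on window.

## Cohort statistics

Paired contrasts use the Wilcoxon signed-rank test, group contrasts the
Mann-Whitney U test; both report the tie-corrected normal-approximation Z
without continuity correction (the variant behind typical published Z
values), two-sided p, and the effect size `r = |Z|/sqrt(N)` with N all pairs
entering the contrast (zero differences are dropped from the statistic but
not from N). Exact enumeration modes (all `2^n` sign assignments, all
`choose(n, n1)` group assignments) exist for small samples and serve as the
testing oracles; at `n <= 10` the normal approximation stays within ~0.1 of
the exact p. CRS-R correlations use Kendall tau-b (scores are heavily tied),
delegated to `stats::cor.test`. Effect sizes are labelled
small/medium/large at 0.1/0.3/0.5; p in (0.05, 0.1] is flagged a trend; no
multiple-testing correction is applied, and reports round to two decimals
(half away from zero).

## The synthetic ward cohort

`generatePatient()` builds per-minute recordings: endogenous activity
`max(0, mesor + amplitude * cos(2*pi*(t - acrophase)/period) + noise)` (or
Poisson draws around the rhythm for count-like data), plus care events from
daily templates — each template has a scheduled clock time, Gaussian
day-to-day jitter, a duration, a daily occurrence probability, and a passive
amplitude *added* to the recorded values. Additivity is the simplest
confound model consistent with treating recorded activity during events as
not the patient's own. The emitted log delays each start by a configurable
latency (default 3 min, safely inside the 5-min nursing pad) to emulate
staff pressing the button late.

No quantitative description of real care-event frequency or duration is
available for this population, so the default schedule
(`defaultCareTemplates()`: three nursing rounds, therapy, an afternoon
visiting window, occasional transfers, ~2-3 event-hours/day) is a plausible
placeholder, clearly labelled as such. Default recordings last 7 days,
matching a typical study week.

`headlineBiasConfig()` encodes the bias-demonstration condition: *weak*
endogenous rhythms free-running at 25 h under a *strong* 24-h care schedule.
"Weak" is implemented as amplitudes of 0.5-2.5 units against epoch noise of
4-10 units — after hourly binning the endogenous signal is faint, yet over
7 days it still yields a significant ~25-h periodogram peak; "strong
schedule" as near-certain daily occurrence with 8-15 min jitter and passive
amplitude ~100, an order of magnitude above patient baselines. (An earlier
draft with amplitudes up to 6 units produced a rhythm *stronger* after
binning than the care signal, which contradicts the condition being
modelled; the ranges were fixed once and then frozen.) Under this condition
the uncorrected data show higher median IS and IV, a peak pinned near 24 h,
and a higher share of patients classified circadian, while the corrected
data recover the 25-h truth — the direction the correction is designed to
expose. What the generator does *not* emulate: physiological waveform shape,
sleep staging, spasticity artifacts, device non-wear beyond the logged
`device_off` events, or any dependence of care intensity on diagnosis (all
simulated patients receive equivalent care). Passing tests therefore
demonstrate the pipeline's behaviour under a clean additive confound, not
the full messiness of real recordings.

## Numerical and design notes

- Problem sizes in the test suite are chosen to keep the full run within a
  few minutes: Monte-Carlo suites use 200 seeds on hourly-binned weeks or
  2-day 10-min series; the bias replication uses 20 patients at 7 days of
  minute data.
- Seeded generation saves and restores the caller's RNG state, so package
  randomness never perturbs a user's session; the same seed reproduces a
  patient bit-identically.
- The exclusion threshold (0.9), warn threshold (0.5), pads, context length
  (10 min), day window (07:00-21:00), `ofac` (100), `alpha` (0.001) and the
  1-h circadian tolerance are all exposed as arguments; the defaults are the
  package's reference configuration.
- Known limitations: IS assumes equally many observations of each clock bin
  (use whole days); the normal-approximation p-values are approximate below
  ~10 observations (use the exact modes); the periodogram's `M` is a
  convention, validated empirically only at the default `ofac`.
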
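#' @include AllGenerics.R
NULL

## Bin a series onto a clock-aligned grid of binMinutes, averaging epochs
## within each bin. Returns bin means, each bin's clock index (0-based,
## position within the 24-h day) and p = bins per day. Incomplete bins at the
## recording edges are dropped.
.binSeries <- function(series, binMinutes) {
  binMinutes <- as.integer(binMinutes)
  es <- epochSeconds(series)
  if ((binMinutes * 60L) %% es != 0L)
    stop("binMinutes must be a multiple of the epoch length")
  if (1440L %% binMinutes != 0L)
    stop("binMinutes must divide 1440")
  perBin <- (binMinutes * 60L) %/% es
  t0 <- as.numeric(startTime(series))
  midnight <- as.numeric(trunc(startTime(series), "days"))
  secSinceMidnight <- (t0 - midnight) + (seq_len(nEpochs(series)) - 1L) * es
  absBin <- floor(secSinceMidnight / (binMinutes * 60))
  v <- activityValues(series)
  counts <- tapply(v, absBin, length)
  keep <- names(counts)[counts == perBin]
  means <- tapply(v, absBin, mean)[keep]
  bins <- as.numeric(keep)
  o <- order(bins)
  p <- 1440L %/% binMinutes
  list(values = as.numeric(means[o]), clock = bins[o] %% p, p = p)
}

.undefined <- function(what) {
  warning(what, " is undefined for a zero-variance series", call. = FALSE)
  NA_real_
}

#' @describeIn interdailyStability Interdaily stability of an activity
#'   series: the extent to which the activity profile repeats from day to
#'   day, i.e. how well the rhythm is entrained to a 24-h zeitgeber. The
#'   series is averaged into clock-aligned bins of `binMinutes`; with `p`
#'   bins per day, `N` bins in total, bin values `x_i`, clock-time means
#'   `xbar_h` and overall mean `xbar`:
#'   `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`.
#'   IS is 0 in expectation for Gaussian noise (up to a 1/n_days bias) and 1
#'   for any pattern that repeats exactly every 24 h. Requires at least two
#'   full days; returns `NA` with a warning for a zero-variance series.
#'
#' @param binMinutes bin width in minutes; 60 is the classical choice, 1
#'   evaluates the indices on the raw per-minute data.
#' @export
#' @examples
#' x <- ActivitySeries(rep(sin(2 * pi * (0:1439) / 1440)^2, 3), "2020-01-06")
#' interdailyStability(x)   # exactly periodic at 24 h -> 1
setMethod("interdailyStability", "ActivitySeries",
  function(x, binMinutes = 60L) {
    b <- .binSeries(x, binMinutes)
    n <- length(b$values)
    if (n < 2L * b$p)
      stop("interdaily stability needs at least two full days of data")
    xbar <- mean(b$values)
    ss <- sum((b$values - xbar)^2)
    if (ss <= 0) return(.undefined("interdaily stability"))
    hmeans <- tapply(b$values, b$clock, mean)
    (n * sum((hmeans - xbar)^2)) / (length(hmeans) * ss)
  })

#' @describeIn intradailyVariability Intradaily variability of an activity
#'   series: fragmentation of the rest-activity pattern, the normalized mean
#'   square of successive bin differences,
#'   `IV = (N * sum_{i>=2} (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i -
#'   xbar)^2)`. IV converges to 0 for a smooth sine wave, is about 2 for
#'   Gaussian noise, and exceeds 2 when a pronounced ultradian (~2-bin)
#'   component is present. Returns `NA` with a warning for a zero-variance
#'   series.
#' @export
setMethod("intradailyVariability", "ActivitySeries",
  function(x, binMinutes = 60L) {
    b <- .binSeries(x, binMinutes)
    n <- length(b$values)
    if (n < 2L) stop("intradaily variability needs at least two bins")
    xbar <- mean(b$values)
    ss <- sum((b$values - xbar)^2)
    if (ss <= 0) return(.undefined("intradaily variability"))
    (n * sum(diff(b$values)^2)) / ((n - 1) * ss)
  })

#' @describeIn dayNightMeans Mean activity separately for daytime
#'   (07:00-21:00 local clock by default) and nighttime (21:00-07:00),
#'   averaged over the whole recording. An epoch belongs to the day window if
#'   its start time falls in `[dayStartHour, nightStartHour)`.
#'
#' @param dayStartHour clock hour at which the day window opens.
#' @param nightStartHour clock hour at which the night window opens.
#' @export
#' @examples
#' s <- ActivitySeries(rep(5, 2880), "2020-01-06")
#' dayNightMeans(s)
setMethod("dayNightMeans", "ActivitySeries",
  function(x, dayStartHour = 7, nightStartHour = 21) {
    es <- epochSeconds(x)
    midnight <- as.numeric(trunc(startTime(x), "days"))
    sec <- (as.numeric(startTime(x)) - midnight) +
      (seq_len(nEpochs(x)) - 1L) * es
    clockH <- (sec / 3600) %% 24
    day <- clockH >= dayStartHour & clockH < nightStartHour
    v <- activityValues(x)
    list(mean_day = mean(v[day]), mean_night = mean(v[!day]))
  })
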
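#' @include AllGenerics.R
NULL

.lombCore <- function(timesHours, values, ofac = 100, alpha = 0.001,
                      periodRangeHours = NULL) {
  stopifnot(length(timesHours) == length(values))
  keep <- is.finite(timesHours) & is.finite(values)
  t <- timesHours[keep]; y <- values[keep]
  if (length(unique(t)) < 3L)
    stop("Lomb-Scargle needs at least 3 distinct sample times")
  if (stats::var(y) <= 0) {
    warning("Lomb-Scargle periodogram is undefined for constant input",
            call. = FALSE)
    return(new("Periodogram", periodsHours = numeric(), power = numeric(),
               pValues = numeric(), ofac = ofac, alpha = alpha,
               nIndepFreq = 0, nUsed = length(y)))
  }
  span <- max(t) - min(t)
  dtMed <- stats::median(diff(sort(unique(t))))
  nyquist <- 1 / (2 * dtMed)
  fmin <- 1 / span
  fmax <- nyquist
  if (!is.null(periodRangeHours)) {
    stopifnot(length(periodRangeHours) == 2L,
              periodRangeHours[1L] < periodRangeHours[2L],
              periodRangeHours[1L] > 0)
    fmin <- max(fmin, 1 / periodRangeHours[2L])
    fmax <- min(fmax, 1 / periodRangeHours[1L])
  }
  if (fmax <= fmin) stop("empty frequency grid for the requested period range")
  df <- 1 / (ofac * span)
  freqs <- seq(fmin, fmax, by = df)
  power <- .lombPower(t, y, 2 * pi * freqs)
  m <- length(freqs) / ofac
  ## Horne-Baliunas-style false-alarm probability of the per-frequency power
  ## under Gaussian noise: FAP = 1 - (1 - exp(-P))^M.
  pvals <- -expm1(m * log1p(-pmin(exp(-power), 1 - 1e-300)))
  pvals <- pmin(pmax(pvals, 0), 1)
  new("Periodogram", periodsHours = 1 / freqs, power = as.numeric(power),
      pValues = pvals, ofac = as.numeric(ofac), alpha = as.numeric(alpha),
      nIndepFreq = m, nUsed = length(y))
}

#' @describeIn lombScargle Periodogram of an activity series. Tolerates
#'   missing epochs (`NA` values are dropped, leaving unevenly sampled input).
#'   The frequency grid runs from 1/span to the (pseudo-)Nyquist frequency
#'   with spacing `1/(ofac * span)`; `periodRangeHours` restricts it, e.g.
#'   `c(3, 48)` to scan only the circadian band and its surroundings.
#'   Per-frequency false-alarm p-values use an effective independent-frequency
#'   count `M = n_grid / ofac`.
#'
#' @param values numeric activity values (only for the numeric-times method).
#' @param ofac oversampling factor (frequency grid density); default 100.
#' @param alpha significance level used downstream for peak filtering;
#'   default 0.001.
#' @param periodRangeHours optional `c(min, max)` trial-period range in hours;
#'   default is the full grid from the recording span down to twice the epoch.
#' @export
#' @examples
#' h <- (0:287) / 12   # 2 days at 5-min sampling, in hours
#' y <- 10 + 5 * cos(2 * pi * h / 24) + rnorm(288)
#' pg <- lombScargle(h, values = y, periodRangeHours = c(3, 47))
#' extractCircadianPeak(pg)$period_hours
setMethod("lombScargle", "ActivitySeries",
  function(x, ofac = 100, alpha = 0.001, periodRangeHours = NULL) {
    hours <- (seq_len(nEpochs(x)) - 1L) * epochSeconds(x) / 3600
    .lombCore(hours, activityValues(x), ofac, alpha, periodRangeHours)
  })

#' @describeIn lombScargle Periodogram of raw (possibly unevenly sampled)
#'   observations; `x` are the sample times in hours.
#' @export
setMethod("lombScargle", "numeric",
  function(x, values, ofac = 100, alpha = 0.001, periodRangeHours = NULL) {
    .lombCore(x, values, ofac, alpha, periodRangeHours)
  })

#' Extract the significant periodogram peak closest to 24 h
#'
#' Finds local maxima of the normalized power (strictly greater than both
#' grid neighbours; for plateaus, the plateau element whose period is nearest
#' the target represents the run), keeps those with false-alarm p-value below
#' the periodogram's `alpha`, and selects the one whose period is closest to
#' `targetHours`. The deviation from 24 h of that peak classifies the series:
#' circadian if a significant peak exists and the deviation is strictly less
#' than `circadianToleranceHours` (a deviation of exactly 1 h is therefore
#' not circadian).
#'
#' @param pg a [Periodogram-class].
#' @param targetHours period the selection is anchored to; default 24.
#' @param circadianToleranceHours classification threshold in hours; default 1.
#' @return list with `period_hours`, `normalized_power_at_peak`, `p_value`,
#'   `deviation_from_24h`, `significant` and `is_circadian`. When no
#'   significant peak exists, the period and deviation are `NA` and both
#'   flags are `FALSE`.
#' @export
extractCircadianPeak <- function(pg, targetHours = 24,
                                 circadianToleranceHours = 1) {
  stopifnot(is(pg, "Periodogram"))
  pw <- pg@power
  empty <- list(period_hours = NA_real_,
                normalized_power_at_peak = NA_real_,
                p_value = NA_real_, deviation_from_24h = NA_real_,
                significant = FALSE, is_circadian = FALSE)
  if (length(pw) < 3L) return(empty)
  ## Compress plateaus so that runs of equal power count as one candidate.
  r <- rle(pw)
  k <- length(r$values)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  isMax <- rep(FALSE, k)
  if (k >= 3L)
    isMax[2:(k - 1L)] <- r$values[2:(k - 1L)] > r$values[1:(k - 2L)] &
      r$values[2:(k - 1L)] > r$values[3:k]
  cand <- integer(0)
  for (j in which(isMax)) {
    idx <- runStart[j]:runEnd[j]
    cand <- c(cand, idx[which.min(abs(pg@periodsHours[idx] - targetHours))])
  }
  cand <- cand[pg@pValues[cand] < pg@alpha]
  if (!length(cand)) return(empty)
  best <- cand[which.min(abs(pg@periodsHours[cand] - targetHours))]
  period <- pg@periodsHours[best]
  dev <- abs(period - 24)
  list(period_hours = period,
       normalized_power_at_peak = pw[best],
       p_value = pg@pValues[best],
       deviation_from_24h = dev,
       significant = TRUE,
       is_circadian = dev < circadianToleranceHours)
}
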
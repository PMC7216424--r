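#' @include AllGenerics.R
NULL

#' @describeIn summarizeSeries One-row circadian summary of a series:
#'   interdaily stability, intradaily variability, the significant
#'   Lomb-Scargle peak closest to 24 h (period, deviation from 24 h,
#'   normalized power, circadian classification) and day/night mean activity.
#'   Metrics that are undefined for the series (e.g. zero variance) are
#'   carried as `NA`, never as silent zeros.
#'
#' @param binMinutes bin width for IS/IV, minutes.
#' @param ofac periodogram oversampling factor.
#' @param alpha significance level for peak filtering.
#' @param lsPeriodRangeHours trial-period range scanned by the periodogram;
#'   the default `c(3, 48)` brackets the circadian band (the peak-selection
#'   rule anchors at 24 h, so remote periods carry no information here) while
#'   keeping the grid, and with it the independent-frequency count entering
#'   the significance filter, tied to the band actually searched.
#' @param circadianToleranceHours deviation threshold (hours) below which the
#'   series is classified circadian.
#' @export
#' @examples
#' p <- generatePatient(rhythmSpec(20, 15, noiseSd = 4), days = 3, seed = 2)
#' summarizeSeries(p@recorded)
setMethod("summarizeSeries", "ActivitySeries",
  function(x, binMinutes = 60L, ofac = 100, alpha = 0.001,
           lsPeriodRangeHours = c(3, 48), circadianToleranceHours = 1) {
    is_ <- tryCatch(suppressWarnings(interdailyStability(x, binMinutes)),
                    error = function(e) NA_real_)
    iv <- tryCatch(suppressWarnings(intradailyVariability(x, binMinutes)),
                   error = function(e) NA_real_)
    pk <- tryCatch({
      pg <- suppressWarnings(
        lombScargle(x, ofac = ofac, alpha = alpha,
                    periodRangeHours = lsPeriodRangeHours))
      extractCircadianPeak(pg, circadianToleranceHours =
                                 circadianToleranceHours)
    }, error = function(e) list(period_hours = NA_real_,
                                normalized_power_at_peak = NA_real_,
                                p_value = NA_real_,
                                deviation_from_24h = NA_real_,
                                significant = FALSE, is_circadian = FALSE))
    dn <- dayNightMeans(x)
    data.frame(patient_id = patientId(x),
               is = is_, iv = iv,
               period_h = pk$period_hours,
               deviation_h = pk$deviation_from_24h,
               norm_power = pk$normalized_power_at_peak,
               peak_significant = pk$significant,
               circadian = pk$is_circadian,
               mean_day = dn$mean_day, mean_night = dn$mean_night,
               stringsAsFactors = FALSE)
  })

#' Summarize a whole cohort of series
#'
#' Applies [summarizeSeries()] to each series and binds the one-row summaries
#' into a per-patient table. Series that fail to summarize are dropped with a
#' message naming the patient and the reason.
#'
#' @param seriesList list of [ActivitySeries-class] /
#'   [CorrectedSeries-class] objects.
#' @param ... passed to [summarizeSeries()].
#' @return data.frame with one row per successfully summarized series.
#' @export
summarizeCohort <- function(seriesList, ...) {
  rows <- lapply(seriesList, function(s) {
    tryCatch(summarizeSeries(s, ...), error = function(e) {
      message("patient ", patientId(s), " excluded from summaries: ",
              conditionMessage(e))
      NULL
    })
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
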
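#' @include AllClasses.R
NULL

#' Accessors for actiward objects
#'
#' @param x an [ActivitySeries-class], [CorrectedSeries-class],
#'   [EventLog-class] or [SimulatedPatient-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("epochSeconds", function(x) standardGeneric("epochSeconds"))

#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("removalMask", function(x) standardGeneric("removalMask"))

#' @rdname accessors
#' @export
setGeneric("imputedFrom", function(x) standardGeneric("imputedFrom"))

#' @rdname accessors
#' @export
setGeneric("removalIntervals", function(x) standardGeneric("removalIntervals"))

#' @rdname accessors
#' @export
setGeneric("removedFraction", function(x) standardGeneric("removedFraction"))

#' Interdaily stability (IS)
#'
#' @param x an [ActivitySeries-class] (or [CorrectedSeries-class]).
#' @param ... passed to methods (`binMinutes`).
#' @export
setGeneric("interdailyStability",
           function(x, ...) standardGeneric("interdailyStability"))

#' Intradaily variability (IV)
#'
#' @param x an [ActivitySeries-class] (or [CorrectedSeries-class]).
#' @param ... passed to methods (`binMinutes`).
#' @export
setGeneric("intradailyVariability",
           function(x, ...) standardGeneric("intradailyVariability"))

#' Day and night mean activity
#'
#' @param x an [ActivitySeries-class] (or [CorrectedSeries-class]).
#' @param ... passed to methods.
#' @export
setGeneric("dayNightMeans", function(x, ...) standardGeneric("dayNightMeans"))

#' Lomb-Scargle periodogram
#'
#' @param x an [ActivitySeries-class], or a numeric vector of sample times in
#'   hours (then supply `values`).
#' @param ... passed to methods.
#' @export
setGeneric("lombScargle", function(x, ...) standardGeneric("lombScargle"))

#' Per-series circadian summary
#'
#' @param x an [ActivitySeries-class] or [CorrectedSeries-class].
#' @param ... passed to methods.
#' @export
setGeneric("summarizeSeries",
           function(x, ...) standardGeneric("summarizeSeries"))

#' Correct an activity series for passive movements
#'
#' @param series an [ActivitySeries-class] (per-minute) or
#'   [CorrectedSeries-class].
#' @param log an [EventLog-class].
#' @param ... passed to methods.
#' @export
setGeneric("correctSeries",
           function(series, log, ...) standardGeneric("correctSeries"))
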
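#' @import methods
NULL

## Event-type vocabulary ------------------------------------------------------

#' Event-type vocabulary
#'
#' Event types mirror the bedside tablet used on the ward: interval events
#' have start and end buttons, point events a single press. Only interval
#' events of the removable types trigger artifact removal; point events
#' (medication, nutrition, lights, eye state) are annotations.
#'
#' @return `eventTypes()`, `pointEventTypes()` and `removableEventTypes()`
#'   return character vectors of type names.
#' @export
#' @examples
#' eventTypes()
eventTypes <- function() {
  c("visit", "nursing", "therapy", "wheelchair", "mobilization_outside",
    "device_off", "crs_r", "medication", "nutrition", "lights_on",
    "lights_off", "eyes_open", "eyes_closed")
}

#' @rdname eventTypes
#' @export
pointEventTypes <- function() {
  c("medication", "nutrition", "lights_on", "lights_off",
    "eyes_open", "eyes_closed")
}

#' @rdname eventTypes
#' @export
removableEventTypes <- function() {
  c("visit", "nursing", "therapy", "wheelchair", "mobilization_outside",
    "device_off", "crs_r")
}

## Internal time helpers ------------------------------------------------------

## All timestamps are timezone-naive local clock time, carried as POSIXct
## in UTC so that arithmetic never crosses DST transitions.
.asTime <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

.formatTime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

## ActivitySeries --------------------------------------------------------------

#' ActivitySeries: a regularly sampled per-epoch activity recording
#'
#' Holds one patient's actigraphy as an ordered vector of nonnegative
#' activity values (arbitrary units) on a regular epoch grid. The timestamp
#' of an epoch labels its start; epoch `i` covers
#' `[startTime + (i-1)*epochSeconds, startTime + i*epochSeconds)`.
#'
#' @slot patientId character(1) identifier.
#' @slot startTime `POSIXct(1)`, timezone-naive local clock time of the first
#'   epoch's start.
#' @slot epochSeconds integer(1), epoch length in seconds; must divide 3600.
#' @slot values numeric vector of nonnegative, finite activity values.
#'
#' @aliases ActivitySeries
#' @export
setClass("ActivitySeries",
  representation(patientId = "character",
                 startTime = "POSIXct",
                 epochSeconds = "integer",
                 values = "numeric"))

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single string")
  if (length(object@startTime) != 1L || is.na(object@startTime))
    msg <- c(msg, "startTime must be a single non-missing timestamp")
  if (length(object@epochSeconds) != 1L || is.na(object@epochSeconds) ||
      object@epochSeconds <= 0L)
    msg <- c(msg, "epochSeconds must be a positive integer")
  else if (3600L %% object@epochSeconds != 0L)
    msg <- c(msg, "epochSeconds must divide 3600")
  if (length(object@values) == 0L)
    msg <- c(msg, "values must be non-empty")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite and non-missing")
  else if (any(object@values < 0))
    msg <- c(msg, "values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an ActivitySeries
#'
#' @param values numeric vector of nonnegative activity values, one per epoch.
#' @param startTime start of the first epoch (POSIXct or ISO-8601 string;
#'   interpreted as timezone-naive local clock time).
#' @param epochSeconds epoch length in seconds (must divide 3600); default 60.
#' @param patientId identifier string.
#' @return An [ActivitySeries-class] object.
#' @export
#' @examples
#' s <- ActivitySeries(c(0, 1, 2), startTime = "2020-01-06T00:00:00")
#' nEpochs(s)
ActivitySeries <- function(values, startTime, epochSeconds = 60L,
                           patientId = "unknown") {
  new("ActivitySeries",
      patientId = as.character(patientId),
      startTime = .asTime(startTime),
      epochSeconds = as.integer(epochSeconds),
      values = as.numeric(values))
}

## EventLog --------------------------------------------------------------------

#' EventLog: typed ward events for one patient
#'
#' A typed log of care events as recorded by bedside staff: interval events
#' (visits, nursing, therapy, wheelchair transfers, mobilizations outside,
#' device off, CRS-R assessments) carry start and end; point events
#' (medication, nutrition, lights, eye state) carry only a start.
#'
#' @slot patientId character(1) identifier.
#' @slot events data.frame with columns `type` (character, see
#'   [eventTypes()]), `start` (POSIXct) and `end` (POSIXct, `NA` for point
#'   events). Overlapping intervals are allowed; they are merged downstream.
#'
#' @aliases EventLog
#' @export
setClass("EventLog",
  representation(patientId = "character", events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  msg <- character()
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single string")
  if (!all(c("type", "start", "end") %in% names(ev)))
    msg <- c(msg, "events must have columns type, start, end")
  else {
    bad <- setdiff(ev$type, eventTypes())
    if (length(bad))
      msg <- c(msg, paste0("unknown event type(s): ",
                           paste(unique(bad), collapse = ", "),
                           "; allowed: ", paste(eventTypes(), collapse = ", ")))
    pt <- ev$type %in% pointEventTypes()
    if (any(!is.na(ev$end[pt])))
      msg <- c(msg, "point events must not carry an end time")
    if (any(is.na(ev$end[!pt])))
      msg <- c(msg, "interval events must carry an end time")
    iv <- !pt & !is.na(ev$end)
    if (any(iv) && any(ev$end[iv] <= ev$start[iv]))
      msg <- c(msg, "interval events must have end > start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventLog
#'
#' @param type character vector of event types (see [eventTypes()]).
#' @param start event start times (POSIXct or ISO-8601 strings).
#' @param end event end times; `NA` for point events.
#' @param patientId identifier string.
#' @return An [EventLog-class] object, sorted by start time.
#' @export
#' @examples
#' EventLog(type = c("nursing", "medication"),
#'          start = c("2020-01-06T10:00:00", "2020-01-06T08:00:00"),
#'          end = c("2020-01-06T10:20:00", NA))
EventLog <- function(type = character(), start = .asTime(character()),
                     end = .asTime(character()), patientId = "unknown") {
  start <- .asTime(start)
  if (length(end) == 0L && length(start) > 0L) end <- rep(NA, length(start))
  end <- .asTime(end)
  ev <- data.frame(type = as.character(type), start = start, end = end,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventLog", patientId = as.character(patientId), events = ev)
}

## CorrectedSeries -------------------------------------------------------------

#' CorrectedSeries: an activity series after passive-movement correction
#'
#' Extends [ActivitySeries-class]: the `values` slot holds the series with
#' removed epochs replaced in place by two-sided median imputation, plus full
#' provenance of what was removed and where each imputed value came from.
#'
#' @slot mask character per-epoch flag, `"observed"` or `"removed_imputed"`.
#' @slot imputedFrom character per-epoch provenance: `"none"`, `"before"`,
#'   `"after"` or `"both"`.
#' @slot intervals data.frame of merged removal intervals with columns
#'   `start`, `end` (POSIXct, epoch-aligned), `start_epoch`, `end_epoch`
#'   (1-based inclusive epoch indices) and `source_types`
#'   (semicolon-separated event types behind the interval).
#' @slot removedFraction numeric(1), share of epochs removed and imputed.
#'
#' @aliases CorrectedSeries
#' @export
setClass("CorrectedSeries",
  contains = "ActivitySeries",
  representation(mask = "character",
                 imputedFrom = "character",
                 intervals = "data.frame",
                 removedFraction = "numeric"))

setValidity("CorrectedSeries", function(object) {
  msg <- character()
  n <- length(object@values)
  if (length(object@mask) != n)
    msg <- c(msg, "mask must have one entry per epoch")
  else if (!all(object@mask %in% c("observed", "removed_imputed")))
    msg <- c(msg, "mask entries must be 'observed' or 'removed_imputed'")
  if (length(object@imputedFrom) != n)
    msg <- c(msg, "imputedFrom must have one entry per epoch")
  else if (!all(object@imputedFrom %in% c("none", "before", "after", "both")))
    msg <- c(msg, "imputedFrom entries must be none/before/after/both")
  if (length(object@removedFraction) != 1L ||
      object@removedFraction < 0 || object@removedFraction > 1)
    msg <- c(msg, "removedFraction must be a single value in [0, 1]")
  else if (length(object@mask) == n &&
           abs(object@removedFraction - mean(object@mask == "removed_imputed")) >
             1e-12)
    msg <- c(msg, "removedFraction must equal the share of removed epochs")
  if (length(msg)) msg else TRUE
})

## SimulatedPatient ------------------------------------------------------------

#' SimulatedPatient: one synthetic ward patient with ground truth
#'
#' Bundles the recorded series (endogenous rhythm plus injected passive
#' activity), the uncontaminated endogenous truth, the (imperfect) event log
#' staff would have produced, the true event windows, and the generating
#' parameters.
#'
#' @slot recorded [ActivitySeries-class] with passive activity added.
#' @slot endogenousTruth [ActivitySeries-class] without any passive activity.
#' @slot log [EventLog-class] as logged (start times delayed by the configured
#'   staff latency).
#' @slot trueEvents data.frame of the actual event windows (`type`, `start`,
#'   `end`), before logging latency.
#' @slot trueSpec list, the `rhythmSpec()` used.
#' @slot seed integer(1) seed that generated the patient.
#'
#' @aliases SimulatedPatient
#' @export
setClass("SimulatedPatient",
  representation(recorded = "ActivitySeries",
                 endogenousTruth = "ActivitySeries",
                 log = "EventLog",
                 trueEvents = "data.frame",
                 trueSpec = "list",
                 seed = "integer"))

setValidity("SimulatedPatient", function(object) {
  msg <- character()
  if (length(object@recorded@values) != length(object@endogenousTruth@values))
    msg <- c(msg, "recorded and endogenousTruth must share epoching")
  if (!identical(object@recorded@startTime, object@endogenousTruth@startTime))
    msg <- c(msg, "recorded and endogenousTruth must share startTime")
  if (any(object@recorded@values < object@endogenousTruth@values - 1e-9))
    msg <- c(msg, "recorded activity must dominate the endogenous truth")
  if (length(msg)) msg else TRUE
})

## Periodogram -----------------------------------------------------------------

#' Periodogram: a normalized Lomb-Scargle periodogram
#'
#' Classical normalized Lomb-Scargle power over a frequency grid with density
#' `ofac` relative to the natural spacing 1/span, plus per-frequency
#' false-alarm p-values based on an effective number of independent
#' frequencies `nIndepFreq`.
#'
#' @slot periodsHours numeric, trial periods in hours, strictly decreasing.
#' @slot power numeric, normalized power at each period (nonnegative).
#' @slot pValues numeric, per-frequency false-alarm probabilities.
#' @slot ofac numeric(1), oversampling factor.
#' @slot alpha numeric(1), significance level used for peak filtering.
#' @slot nIndepFreq numeric(1), effective independent-frequency count M.
#' @slot nUsed integer(1), number of samples the periodogram was computed on.
#'
#' @aliases Periodogram
#' @export
setClass("Periodogram",
  representation(periodsHours = "numeric",
                 power = "numeric",
                 pValues = "numeric",
                 ofac = "numeric",
                 alpha = "numeric",
                 nIndepFreq = "numeric",
                 nUsed = "integer"))

setValidity("Periodogram", function(object) {
  msg <- character()
  if (length(object@power) != length(object@periodsHours) ||
      length(object@pValues) != length(object@periodsHours))
    msg <- c(msg, "periodsHours, power and pValues must have equal length")
  if (length(object@periodsHours) > 1L && any(diff(object@periodsHours) >= 0))
    msg <- c(msg, "periodsHours must be strictly decreasing")
  if (any(object@power < 0))
    msg <- c(msg, "power must be nonnegative")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
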
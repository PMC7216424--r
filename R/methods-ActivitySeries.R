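#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("patientId", "ActivitySeries", function(x) x@patientId)

#' @rdname accessors
#' @export
setMethod("patientId", "EventLog", function(x) x@patientId)

#' @rdname accessors
#' @export
setMethod("patientId", "SimulatedPatient", function(x) x@recorded@patientId)

#' @rdname accessors
#' @export
setMethod("startTime", "ActivitySeries", function(x) x@startTime)

#' @rdname accessors
#' @export
setMethod("epochSeconds", "ActivitySeries", function(x) x@epochSeconds)

#' @rdname accessors
#' @export
setMethod("activityValues", "ActivitySeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("nEpochs", "ActivitySeries", function(x) length(x@values))

#' @rdname accessors
#' @export
setMethod("epochTimes", "ActivitySeries", function(x) {
  x@startTime + (seq_along(x@values) - 1L) * as.numeric(x@epochSeconds)
})

#' @rdname accessors
#' @export
setMethod("events", "EventLog", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("nEvents", "EventLog", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setMethod("removalMask", "CorrectedSeries", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("imputedFrom", "CorrectedSeries", function(x) x@imputedFrom)

#' @rdname accessors
#' @export
setMethod("removalIntervals", "CorrectedSeries", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("removedFraction", "CorrectedSeries", function(x) x@removedFraction)

setMethod("show", "ActivitySeries", function(object) {
  spanH <- length(object@values) * object@epochSeconds / 3600
  cat("ActivitySeries for patient", object@patientId, "\n",
      " ", length(object@values), "epochs of", object@epochSeconds,
      "s (", format(round(spanH, 1)), "h ) starting",
      .formatTime(object@startTime), "\n",
      "  activity range [", format(signif(min(object@values), 4)), ",",
      format(signif(max(object@values), 4)), "]\n")
  invisible(NULL)
})

setMethod("show", "EventLog", function(object) {
  cat("EventLog for patient", object@patientId, "with",
      nrow(object@events), "events\n")
  if (nrow(object@events)) {
    tab <- table(object@events$type)
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "CorrectedSeries", function(object) {
  callNextMethod()
  cat("  corrected:", sum(object@mask == "removed_imputed"),
      "epochs removed and imputed (",
      sprintf("%.1f%%", 100 * object@removedFraction), ") across",
      nrow(object@intervals), "intervals\n")
  invisible(NULL)
})

setMethod("show", "SimulatedPatient", function(object) {
  cat("SimulatedPatient", object@recorded@patientId,
      "( seed", object@seed, ")\n")
  show(object@recorded)
  cat("  true events:", nrow(object@trueEvents),
      "; logged events:", nrow(object@log@events), "\n")
  invisible(NULL)
})

setMethod("show", "Periodogram", function(object) {
  cat("Lomb-Scargle Periodogram:", length(object@power), "frequencies,",
      "periods", format(round(min(object@periodsHours), 2)), "-",
      format(round(max(object@periodsHours), 2)), "h, ofac =", object@ofac,
      ", alpha =", object@alpha, "\n")
  i <- which.max(object@power)
  cat("  max power", format(signif(object@power[i], 4)), "at",
      format(round(object@periodsHours[i], 3)), "h (p =",
      format(signif(object@pValues[i], 3)), ")\n")
  invisible(NULL)
})
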
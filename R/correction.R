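#' @include AllGenerics.R
NULL

#' Padding policy for event-driven removal
#'
#' Minutes removed before and after each logged event, by event type. The
#' defaults absorb late/early button presses by bedside staff: 5 min around
#' nursing activities and 10 min around visits and wheelchair transfers;
#' the remaining removable types get no extra padding by default but are
#' configurable.
#'
#' @param ... named overrides, each a numeric `c(before, after)` pair in
#'   minutes, e.g. `therapy = c(5, 5)`.
#' @return A named list mapping event type to `c(before, after)` minutes.
#' @export
#' @examples
#' defaultPaddingPolicy()$nursing
#' defaultPaddingPolicy(therapy = c(5, 5))
defaultPaddingPolicy <- function(...) {
  policy <- list(nursing = c(5, 5), visit = c(10, 10), wheelchair = c(10, 10),
                 therapy = c(0, 0), mobilization_outside = c(0, 0),
                 device_off = c(0, 0), crs_r = c(0, 0))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% removableEventTypes())
      stop("not a removable event type: ", nm)
    pads <- as.numeric(over[[nm]])
    if (length(pads) != 2L || any(pads < 0))
      stop("padding for ", nm, " must be a nonnegative c(before, after) pair")
    policy[[nm]] <- pads
  }
  policy
}

#' Downsample a sub-minute activity series to one value per minute
#'
#' Aggregates raw epochs into per-minute values (sum by default, matching
#' count-like activity semantics; `"mean"` optionally). A trailing partial
#' minute is dropped.
#'
#' @param raw an [ActivitySeries-class] with `epochSeconds < 60`.
#' @param aggregate `"sum"` or `"mean"`.
#' @return A per-minute [ActivitySeries-class].
#' @export
#' @examples
#' raw <- ActivitySeries(rep(1, 120), "2020-01-06", epochSeconds = 2)
#' activityValues(downsampleToMinutes(raw))   # 30 30
downsampleToMinutes <- function(raw, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(raw, "ActivitySeries"))
  es <- epochSeconds(raw)
  if (es >= 60L) stop("series already at one-minute (or coarser) epochs")
  if (60L %% es != 0L) stop("raw epoch length must divide 60 seconds")
  perMin <- 60L %/% es
  n <- nEpochs(raw)
  nMin <- n %/% perMin
  if (nMin == 0L) stop("series shorter than one minute")
  v <- activityValues(raw)[seq_len(nMin * perMin)]
  m <- matrix(v, nrow = perMin)
  out <- if (aggregate == "sum") colSums(m) else colMeans(m)
  ActivitySeries(out, startTime = startTime(raw), epochSeconds = 60L,
                 patientId = patientId(raw))
}

## Snap an event window [start, end) (POSIXct/numeric seconds) outward to
## 1-based inclusive epoch indices on the series grid; NULL if fully outside.
.snapToEpochs <- function(start, end, t0, epochSec, n) {
  s <- floor((as.numeric(start) - t0) / epochSec) + 1
  e <- ceiling((as.numeric(end) - t0) / epochSec)
  s <- max(s, 1)
  e <- min(e, n)
  if (e < s) return(NULL)
  c(as.integer(s), as.integer(e))
}

#' Build merged removal intervals from an event log
#'
#' Expands every interval event of a removable type (visits, nursing,
#' therapy, wheelchair, mobilizations outside, device off, CRS-R) by its
#' type-specific padding, clips it to the recording span, snaps it outward to
#' epoch boundaries, and merges overlapping or adjacent intervals into
#' maximal disjoint removal intervals. Point events never cause removal;
#' events entirely outside the recording are skipped with a message.
#'
#' @param log an [EventLog-class].
#' @param policy padding policy from [defaultPaddingPolicy()].
#' @param series the [ActivitySeries-class] the removal applies to.
#' @param extraIntervals optional data.frame with `start` and `end`
#'   (POSIXct or ISO strings): additional removal windows, e.g. from visual
#'   screening of residual artifacts; merged like events, with source type
#'   `"manual"`.
#' @return data.frame with one row per merged interval: `start`, `end`
#'   (epoch-aligned POSIXct), `start_epoch`, `end_epoch` (1-based inclusive)
#'   and `source_types` (semicolon-separated).
#' @export
#' @examples
#' s <- ActivitySeries(rep(1, 1440), "2020-01-06")
#' log <- EventLog("nursing", "2020-01-06T10:00:00", "2020-01-06T10:20:00")
#' buildRemovalIntervals(log, defaultPaddingPolicy(), s)[, c("start", "end")]
buildRemovalIntervals <- function(log, policy = defaultPaddingPolicy(),
                                  series, extraIntervals = NULL) {
  stopifnot(is(log, "EventLog"), is(series, "ActivitySeries"))
  es <- epochSeconds(series)
  t0 <- as.numeric(startTime(series))
  n <- nEpochs(series)
  ev <- events(log)
  ev <- ev[ev$type %in% removableEventTypes() & !is.na(ev$end), , drop = FALSE]

  starts <- integer(); ends <- integer(); types <- character()
  addWindow <- function(s, e, type) {
    snapped <- .snapToEpochs(s, e, t0, es, n)
    if (is.null(snapped)) {
      message("event '", type, "' at ", .formatTime(.asTime(s)),
              " lies outside the recording span; ignored")
      return(invisible(NULL))
    }
    starts <<- c(starts, snapped[1L])
    ends <<- c(ends, snapped[2L])
    types <<- c(types, type)
  }
  for (i in seq_len(nrow(ev))) {
    pads <- policy[[ev$type[i]]]
    if (is.null(pads)) pads <- c(0, 0)
    addWindow(as.numeric(ev$start[i]) - pads[1L] * 60,
              as.numeric(ev$end[i]) + pads[2L] * 60, ev$type[i])
  }
  if (!is.null(extraIntervals) && nrow(extraIntervals)) {
    for (i in seq_len(nrow(extraIntervals)))
      addWindow(.asTime(extraIntervals$start[i]),
                .asTime(extraIntervals$end[i]), "manual")
  }
  if (!length(starts)) {
    return(data.frame(start = .asTime(character()), end = .asTime(character()),
                      start_epoch = integer(), end_epoch = integer(),
                      source_types = character()))
  }
  ir <- IRanges::IRanges(start = starts, end = ends)
  red <- IRanges::reduce(ir, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  srcs <- vapply(seq_along(red), function(i) {
    paste(sort(unique(types[revmap[[i]]])), collapse = ";")
  }, character(1))
  se <- IRanges::start(red)
  ee <- IRanges::end(red)
  data.frame(
    start = .asTime(as.POSIXct(t0 + (se - 1) * es, origin = "1970-01-01",
                               tz = "UTC")),
    end = .asTime(as.POSIXct(t0 + ee * es, origin = "1970-01-01", tz = "UTC")),
    start_epoch = se, end_epoch = ee, source_types = srcs)
}

#' Two-sided median imputation for one removal interval
#'
#' Replaces the first half (rounded up) of the interval's epochs with the
#' median of up to `contextMinutes` of non-removed activity immediately
#' preceding the interval, and the second half with the median of up to
#' `contextMinutes` of non-removed activity immediately following it. Context
#' windows skip epochs that belong to other removal intervals (supply
#' `removedMask`), because logged event bounds are unreliable and padded
#' neighbours must not contaminate the medians. If one side has no usable
#' context (interval at the recording boundary), the other side's median is
#' used throughout; if neither side has context the series is uncorrectable.
#'
#' @param series an [ActivitySeries-class].
#' @param interval integer `c(start_epoch, end_epoch)` (1-based inclusive) or
#'   a one-row data.frame from [buildRemovalIntervals()].
#' @param contextMinutes context window length per side, in minutes.
#' @param removedMask optional logical per-epoch vector marking all removed
#'   epochs (defaults to just this interval).
#' @return list with `values` (imputed values for the interval's epochs) and
#'   `from` (per-epoch `"before"`/`"after"` provenance).
#' @export
#' @examples
#' s <- ActivitySeries(c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 0, 0, 0, 0,
#'                       rep(100, 10)), "2020-01-06")
#' imputeInterval(s, c(11, 14))$values   # 11 11 100 100
imputeInterval <- function(series, interval, contextMinutes = 10L,
                           removedMask = NULL) {
  stopifnot(is(series, "ActivitySeries"))
  if (is.data.frame(interval))
    interval <- c(interval$start_epoch[1L], interval$end_epoch[1L])
  s <- as.integer(interval[1L]); e <- as.integer(interval[2L])
  n <- nEpochs(series)
  if (s < 1L || e > n || e < s) stop("interval outside the series span")
  v <- activityValues(series)
  if (is.null(removedMask)) {
    removedMask <- rep(FALSE, n)
    removedMask[s:e] <- TRUE
  }
  ctxN <- max(1L, as.integer(round(contextMinutes * 60 / epochSeconds(series))))

  collect <- function(from, step) {
    out <- numeric(0)
    i <- from
    while (i >= 1L && i <= n && length(out) < ctxN) {
      if (!removedMask[i]) out <- c(out, v[i])
      i <- i + step
    }
    out
  }
  pre <- collect(s - 1L, -1L)
  post <- collect(e + 1L, 1L)
  if (!length(pre) && !length(post))
    stop("uncorrectable series: no context on either side of the interval")
  len <- e - s + 1L
  nFirst <- as.integer(ceiling(len / 2))
  from <- c(rep("before", nFirst), rep("after", len - nFirst))
  vals <- numeric(len)
  preMed <- if (length(pre)) stats::median(pre) else NA_real_
  postMed <- if (length(post)) stats::median(post) else NA_real_
  if (!length(pre)) {
    vals[] <- postMed; from[] <- "after"
  } else if (!length(post)) {
    vals[] <- preMed; from[] <- "before"
  } else {
    vals[from == "before"] <- preMed
    vals[from == "after"] <- postMed
  }
  list(values = vals, from = from)
}

.correctActivitySeries <- function(series, log,
                                   policy = defaultPaddingPolicy(),
                                   extraIntervals = NULL,
                                   contextMinutes = 10L,
                                   warnFraction = 0.5, errorFraction = 0.9) {
  iv <- buildRemovalIntervals(log, policy, series, extraIntervals)
  n <- nEpochs(series)
  mask <- rep("observed", n)
  impFrom <- rep("none", n)
  vals <- activityValues(series)
  removed <- rep(FALSE, n)
  for (i in seq_len(nrow(iv))) removed[iv$start_epoch[i]:iv$end_epoch[i]] <- TRUE
  frac <- mean(removed)
  if (frac > errorFraction)
    stop(sprintf(paste0("uncorrectable series: %.1f%% of epochs would be ",
                        "removed (threshold %.0f%%); exclude this recording"),
                 100 * frac, 100 * errorFraction))
  if (frac > warnFraction)
    warning(sprintf("more than %.0f%% of epochs removed (%.1f%%); treat %s",
                    100 * warnFraction, 100 * frac,
                    "the corrected series with caution"))
  for (i in seq_len(nrow(iv))) {
    idx <- iv$start_epoch[i]:iv$end_epoch[i]
    imp <- imputeInterval(series, c(iv$start_epoch[i], iv$end_epoch[i]),
                          contextMinutes = contextMinutes,
                          removedMask = removed)
    vals[idx] <- imp$values
    impFrom[idx] <- imp$from
    mask[idx] <- "removed_imputed"
  }
  new("CorrectedSeries",
      patientId = patientId(series), startTime = startTime(series),
      epochSeconds = epochSeconds(series), values = vals,
      mask = mask, imputedFrom = impFrom, intervals = iv,
      removedFraction = mean(mask == "removed_imputed"))
}

#' @describeIn correctSeries Correct a per-minute activity series: build
#'   padded, merged removal intervals from the event log (plus any
#'   `extraIntervals` standing in for visual screening of residual
#'   artifacts), impute each interval two-sidedly with context medians, and
#'   return the series with full provenance. Errors if more than
#'   `errorFraction` of epochs would be removed (such recordings carry too
#'   little genuine activity to analyse) and warns above `warnFraction`.
#'
#' @param policy padding policy, see [defaultPaddingPolicy()].
#' @param extraIntervals optional data.frame of additional removal windows
#'   (`start`, `end`), e.g. manually screened residual artifacts.
#' @param contextMinutes context window per side for median imputation.
#' @param warnFraction warn when the removed fraction exceeds this.
#' @param errorFraction error when the removed fraction exceeds this.
#' @export
setMethod("correctSeries", signature("ActivitySeries", "EventLog"),
  function(series, log, policy = defaultPaddingPolicy(),
           extraIntervals = NULL, contextMinutes = 10L,
           warnFraction = 0.5, errorFraction = 0.9) {
    .correctActivitySeries(series, log, policy, extraIntervals,
                           contextMinutes, warnFraction, errorFraction)
  })

#' @describeIn correctSeries Re-correcting an already corrected series with
#'   the same log is the identity (idempotence): the underlying activity is
#'   re-masked and re-imputed from the same untouched context epochs.
#' @export
setMethod("correctSeries", signature("CorrectedSeries", "EventLog"),
  function(series, log, policy = defaultPaddingPolicy(),
           extraIntervals = NULL, contextMinutes = 10L,
           warnFraction = 0.5, errorFraction = 0.9) {
    plain <- ActivitySeries(activityValues(series), startTime(series),
                            epochSeconds(series), patientId(series))
    .correctActivitySeries(plain, log, policy, extraIntervals,
                           contextMinutes, warnFraction, errorFraction)
  })

#' Removal accounting for a corrected series
#'
#' @param corrected a [CorrectedSeries-class].
#' @return list with `overall` (fraction of epochs removed) and `perType`
#'   (named fractions; epochs of merged intervals are attributed to every
#'   source type behind the interval, so per-type fractions can overlap).
#' @export
removedFractionReport <- function(corrected) {
  stopifnot(is(corrected, "CorrectedSeries"))
  n <- nEpochs(corrected)
  iv <- removalIntervals(corrected)
  types <- c(removableEventTypes(), "manual")
  perType <- stats::setNames(numeric(length(types)), types)
  for (ty in types) {
    hit <- rep(FALSE, n)
    for (i in seq_len(nrow(iv))) {
      if (ty %in% strsplit(iv$source_types[i], ";", fixed = TRUE)[[1L]])
        hit[iv$start_epoch[i]:iv$end_epoch[i]] <- TRUE
    }
    perType[[ty]] <- mean(hit)
  }
  list(overall = removedFraction(corrected), perType = perType)
}
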
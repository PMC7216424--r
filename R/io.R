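#' @include AllClasses.R
NULL

#' Read a per-epoch activity CSV
#'
#' Expects a comma-separated file with header columns `timestamp` (ISO-8601,
#' timezone-naive local clock) and `activity` (nonnegative). Timestamps must
#' be strictly increasing with constant spacing; the epoch length is inferred
#' from that spacing. An optional `patient_id` column overrides `patientId`.
#'
#' @param path file path.
#' @param patientId identifier used when the file has no `patient_id` column;
#'   defaults to the file name without extension.
#' @return An [ActivitySeries-class].
#' @seealso [writeActivityCsv()]
#' @export
readActivityCsv <- function(path,
                            patientId = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "activity") %in% names(df)))
    stop("activity CSV must have columns 'timestamp' and 'activity': ", path)
  ts <- .asTime(df$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1L], " of ", path)
  if (nrow(df) >= 2L) {
    d <- diff(as.numeric(ts))
    bad <- which(d <= 0)
    if (length(bad))
      stop("timestamps not strictly increasing at row ", bad[1L] + 1L,
           " of ", path)
    gap <- which(abs(d - d[1L]) > 1e-6)
    if (length(gap))
      stop("irregular timestamp spacing at row ", gap[1L] + 1L, " of ", path,
           " (expected ", d[1L], " s, found ", d[gap[1L]], " s)")
    epochSeconds <- as.integer(round(d[1L]))
  } else {
    epochSeconds <- 60L
  }
  if (any(df$activity < 0, na.rm = TRUE))
    stop("negative activity value at row ", which(df$activity < 0)[1L],
         " of ", path)
  if ("patient_id" %in% names(df)) patientId <- df$patient_id[1L]
  ActivitySeries(df$activity, startTime = ts[1L],
                 epochSeconds = epochSeconds, patientId = patientId)
}

#' Write a per-epoch activity CSV
#'
#' Inverse of [readActivityCsv()]; round-trips losslessly.
#'
#' @param series an [ActivitySeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeActivityCsv <- function(series, path) {
  stopifnot(is(series, "ActivitySeries"))
  df <- data.frame(timestamp = .formatTime(epochTimes(series)),
                   activity = activityValues(series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event log (CSV or JSON)
#'
#' CSV files need header columns `type,start,end`; an empty `end` marks a
#' point event. JSON files hold an array of objects with the same fields.
#' Event types must belong to [eventTypes()]; interval events must satisfy
#' `end > start`.
#'
#' @param path file path (`.json` is parsed as JSON, anything else as CSV).
#' @param patientId identifier used when the file has no `patient_id` column.
#' @return An [EventLog-class].
#' @seealso [writeEventLog()]
#' @export
readEventLog <- function(path,
                         patientId = sub("\\.[^.]*$", "", basename(path))) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON event logs requires the 'jsonlite' package")
    df <- as.data.frame(jsonlite::fromJSON(path))
    if (!"end" %in% names(df)) df$end <- NA_character_
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  if (!all(c("type", "start") %in% names(df)))
    stop("event log must have columns 'type' and 'start': ", path)
  if (!"end" %in% names(df)) df$end <- NA_character_
  df$end[!is.na(df$end) & !nzchar(trimws(df$end))] <- NA_character_
  bad <- setdiff(df$type, eventTypes())
  if (length(bad))
    stop("unknown event type(s) in ", path, ": ",
         paste(unique(bad), collapse = ", "), "; allowed: ",
         paste(eventTypes(), collapse = ", "))
  if ("patient_id" %in% names(df) && nrow(df)) patientId <- df$patient_id[1L]
  EventLog(type = df$type, start = .asTime(df$start), end = .asTime(df$end),
           patientId = patientId)
}

#' Write an event log CSV
#'
#' Inverse of [readEventLog()]; round-trips losslessly.
#'
#' @param log an [EventLog-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(log, path) {
  stopifnot(is(log, "EventLog"))
  ev <- events(log)
  df <- data.frame(type = ev$type,
                   start = .formatTime(ev$start),
                   end = ifelse(is.na(ev$end), "", .formatTime(ev$end)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
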
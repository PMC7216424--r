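#' @include io.R
NULL

#' Read a cohort metadata CSV
#'
#' Cohort metadata mirrors the demographic table of a disorders-of-
#' consciousness study: one row per patient with columns `patient_id`, `age`,
#' `gender` (M/F), `etiology` (TBI/NTBI), `months_since_injury`, `diagnosis`
#' (UWS/MCS/EMCS) and `crs_r_sum` (0-23). An optional logical `excluded`
#' column flags patients dropped from analysis. A `diagnosis_group` column is
#' derived, pooling MCS and EMCS into a single (minimally) conscious group.
#'
#' @param path file path.
#' @return A data.frame with one row per patient and a derived
#'   `diagnosis_group` factor (`UWS` vs `MCS_EMCS`).
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "age", "gender", "etiology", "months_since_injury",
           "diagnosis", "crs_r_sum")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in cohort CSV")
  if (!all(df$gender %in% c("M", "F")))
    stop("gender must be M or F")
  if (!all(df$etiology %in% c("TBI", "NTBI")))
    stop("etiology must be TBI or NTBI")
  if (!all(df$diagnosis %in% c("UWS", "MCS", "EMCS")))
    stop("diagnosis must be UWS, MCS or EMCS")
  if (any(df$crs_r_sum < 0 | df$crs_r_sum > 23))
    stop("crs_r_sum must lie in 0..23")
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  df$diagnosis_group <- factor(
    ifelse(df$diagnosis == "UWS", "UWS", "MCS_EMCS"),
    levels = c("UWS", "MCS_EMCS"))
  df
}

#' Packaged demographic cohort table
#'
#' Returns the packaged 30-patient demographic table of the long-term-care
#' cohort the package's defaults are modelled on: 19 patients with
#' unresponsive wakefulness syndrome (UWS), 7 in a minimally conscious state
#' (MCS) and 4 in exit MCS (EMCS), with age, gender, etiology (traumatic vs
#' non-traumatic brain injury), months since injury and best CRS-R sum score.
#' Patient P26 carries `excluded = TRUE`: after passive-movement correction
#' hardly any of that recording remained, so the analyses run on the other
#' 29 patients.
#'
#' @param dropExcluded if `TRUE`, rows flagged `excluded` are removed.
#' @return A data.frame as from [readCohortCsv()].
#' @export
#' @examples
#' cohort <- loadCohortTable()
#' nrow(cohort)                       # 30
#' table(loadCohortTable(TRUE)$diagnosis)
loadCohortTable <- function(dropExcluded = FALSE) {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "actiward", mustWork = TRUE)
  df <- readCohortCsv(path)
  if (dropExcluded) df <- df[!df$excluded, , drop = FALSE]
  rownames(df) <- NULL
  df
}
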
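#' @include AllClasses.R
NULL

#' Specify an endogenous activity rhythm
#'
#' Parameters of the simulated patient's own ("true") motor activity: a
#' sinusoid of configurable period, amplitude and peak clock time riding on a
#' baseline (mesor), plus noise, truncated at zero to respect count-like
#' nonnegative activity.
#'
#' @param mesor nonnegative baseline activity level (arbitrary units).
#' @param amplitude nonnegative sinusoid amplitude; for the truncated-Gaussian
#'   noise family it must not exceed `mesor`, which keeps the mean structure
#'   nonnegative.
#' @param periodHours endogenous period in hours, in (1, 48). 24 for an
#'   entrained patient; free-running human pacemakers average about 24.2 h.
#' @param acrophaseHours clock time (hours, 0-24) of the activity peak.
#' @param noiseSd standard deviation of the additive Gaussian epoch noise
#'   (ignored for the `"poisson_like"` family, where dispersion follows the
#'   mean).
#' @param noiseFamily `"gaussian_truncated_at_zero"` (additive Gaussian noise,
#'   values truncated at zero) or `"poisson_like"` (each epoch drawn Poisson
#'   with the rhythm as its mean).
#' @param rhythmPresent if `FALSE`, the amplitude is forced to 0 (an
#'   arrhythmic patient).
#' @return A list of class `"RhythmSpec"`.
#' @export
#' @examples
#' rhythmSpec(mesor = 10, amplitude = 4, periodHours = 24, noiseSd = 5)
rhythmSpec <- function(mesor, amplitude, periodHours = 24,
                       acrophaseHours = 15, noiseSd = 0,
                       noiseFamily = c("gaussian_truncated_at_zero",
                                       "poisson_like"),
                       rhythmPresent = TRUE) {
  noiseFamily <- match.arg(noiseFamily)
  if (!rhythmPresent) amplitude <- 0
  stopifnot(mesor >= 0, amplitude >= 0, noiseSd >= 0,
            periodHours > 1, periodHours < 48)
  if (noiseFamily == "gaussian_truncated_at_zero" && amplitude > mesor)
    stop("amplitude must not exceed mesor for truncated-Gaussian noise")
  structure(list(mesor = mesor, amplitude = amplitude,
                 periodHours = periodHours, acrophaseHours = acrophaseHours,
                 noiseSd = noiseSd, noiseFamily = noiseFamily,
                 rhythmPresent = rhythmPresent),
            class = "RhythmSpec")
}

#' Specify a scheduled care-event template
#'
#' Describes one recurring passive-movement source on the ward (nursing
#' round, visiting time, therapy session, wheelchair transfer): a clock time
#' around which the event occurs each day, its duration, day-to-day timing
#' jitter, the passive activity it injects into the recording, its daily
#' occurrence probability, and how late staff press the "start" button on the
#' bedside tablet.
#'
#' @param eventType one of [removableEventTypes()].
#' @param clockTime scheduled start, either hours since midnight (numeric) or
#'   an `"HH:MM"` string.
#' @param durationMinutes event duration (> 0).
#' @param jitterSdMinutes SD of the Gaussian day-to-day start-time jitter.
#' @param passiveAmplitude activity added to every recorded epoch inside the
#'   event window (arbitrary units).
#' @param occurrenceProbability probability in \[0, 1\] that the event takes
#'   place on a given day.
#' @param logStartLatencyMinutes how many minutes late the event's start is
#'   logged (staff tend to press the button after they have started handling
#'   the patient; the removal padding exists to absorb exactly this).
#' @return A list of class `"CareTemplate"`.
#' @export
#' @examples
#' careTemplate("nursing", "07:00", durationMinutes = 30, passiveAmplitude = 80)
careTemplate <- function(eventType, clockTime, durationMinutes,
                         jitterSdMinutes = 10, passiveAmplitude = 80,
                         occurrenceProbability = 1,
                         logStartLatencyMinutes = 3) {
  stopifnot(eventType %in% removableEventTypes(),
            durationMinutes > 0, jitterSdMinutes >= 0, passiveAmplitude >= 0,
            occurrenceProbability >= 0, occurrenceProbability <= 1,
            logStartLatencyMinutes >= 0)
  if (is.character(clockTime)) {
    hm <- as.numeric(strsplit(clockTime, ":", fixed = TRUE)[[1L]])
    clockTime <- hm[1L] + hm[2L] / 60
  }
  stopifnot(clockTime >= 0, clockTime < 24)
  structure(list(eventType = eventType, clockTime = clockTime,
                 durationMinutes = durationMinutes,
                 jitterSdMinutes = jitterSdMinutes,
                 passiveAmplitude = passiveAmplitude,
                 occurrenceProbability = occurrenceProbability,
                 logStartLatencyMinutes = logStartLatencyMinutes),
            class = "CareTemplate")
}

#' Default daily care schedule
#'
#' A plausible long-term-care ward routine: three nursing rounds, one therapy
#' session, an afternoon visiting window and occasional wheelchair transfers.
#' Real care-event frequencies and durations vary between wards and are not
#' quantitatively documented for this population; these defaults are
#' placeholders chosen to total roughly 2-3 event hours per day and should be
#' adapted to the ward being emulated.
#'
#' @param passiveAmplitude activity injected during events (shared by all
#'   templates); default 80 arbitrary units, large relative to the default
#'   patient baselines so that passive movements dominate true activity.
#' @return A list of [careTemplate()] objects.
#' @export
defaultCareTemplates <- function(passiveAmplitude = 80) {
  list(
    careTemplate("nursing", "06:45", 30, jitterSdMinutes = 10,
                 passiveAmplitude = passiveAmplitude),
    careTemplate("nursing", "12:00", 20, jitterSdMinutes = 10,
                 passiveAmplitude = passiveAmplitude),
    careTemplate("nursing", "19:30", 25, jitterSdMinutes = 10,
                 passiveAmplitude = passiveAmplitude),
    careTemplate("therapy", "10:00", 30, jitterSdMinutes = 15,
                 passiveAmplitude = passiveAmplitude,
                 occurrenceProbability = 5 / 7),
    careTemplate("visit", "15:00", 60, jitterSdMinutes = 20,
                 passiveAmplitude = passiveAmplitude,
                 occurrenceProbability = 0.6),
    careTemplate("wheelchair", "14:00", 45, jitterSdMinutes = 15,
                 passiveAmplitude = passiveAmplitude,
                 occurrenceProbability = 0.3))
}

#' Simulate one ward patient
#'
#' Generates a per-minute recording of `days` days: the endogenous rhythm
#' (`max(0, mesor + amplitude * cos(2 * pi * (t - acrophase) / period) +
#' noise)` at each minute, or a Poisson draw around the rhythm), plus, for
#' each day and care template, a possible event whose passive activity is
#' added to the recorded series, and an event-log entry whose start is
#' delayed by the template's logging latency. The same seed reproduces the
#' patient bit-identically.
#'
#' @param spec a [rhythmSpec()].
#' @param templates list of [careTemplate()] objects (may be empty).
#' @param days number of days to simulate; at least 2 (the periodogram needs
#'   two cycles).
#' @param seed integer seed.
#' @param patientId identifier string.
#' @param startTime start of the recording (defaults to a Monday midnight).
#' @return A [SimulatedPatient-class].
#' @export
#' @examples
#' p <- generatePatient(rhythmSpec(10, 4, noiseSd = 3),
#'                      defaultCareTemplates(), days = 2, seed = 1)
#' p
generatePatient <- function(spec, templates = list(), days = 7L, seed = 1L,
                            patientId = "SIM", startTime = "2020-01-06") {
  stopifnot(inherits(spec, "RhythmSpec"))
  days <- as.integer(days)
  if (days < 2L)
    stop("days must be >= 2 (the periodogram needs at least two cycles)")
  startTime <- .asTime(startTime)
  nMin <- days * 1440L
  t0 <- as.numeric(startTime)
  midnight <- as.numeric(trunc(startTime, "days"))
  clockH <- (t0 - midnight) / 3600 + (seq_len(nMin) - 1L) / 60

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  meanCurve <- spec$mesor + spec$amplitude *
    cos(2 * pi * (clockH - spec$acrophaseHours) / spec$periodHours)
  if (spec$noiseFamily == "poisson_like") {
    endo <- stats::rpois(nMin, pmax(0, meanCurve))
  } else {
    endo <- pmax(0, meanCurve + stats::rnorm(nMin, 0, spec$noiseSd))
  }

  recorded <- endo
  trueEv <- list()
  logEv <- list()
  endT <- t0 + nMin * 60
  for (d in seq_len(days) - 1L) {
    for (tmpl in templates) {
      u <- stats::runif(1L)
      jit <- stats::rnorm(1L, 0, tmpl$jitterSdMinutes)
      if (u > tmpl$occurrenceProbability) next
      evStart <- midnight + d * 86400 + (tmpl$clockTime * 60 + jit) * 60
      evEnd <- evStart + tmpl$durationMinutes * 60
      evStart <- max(evStart, t0)
      evEnd <- min(evEnd, endT)
      if (evEnd <= evStart) next
      i <- which(t0 + (seq_len(nMin) - 1L) * 60 >= evStart &
                 t0 + (seq_len(nMin) - 1L) * 60 < evEnd)
      recorded[i] <- recorded[i] + tmpl$passiveAmplitude
      trueEv[[length(trueEv) + 1L]] <-
        data.frame(type = tmpl$eventType,
                   start = as.POSIXct(evStart, origin = "1970-01-01",
                                      tz = "UTC"),
                   end = as.POSIXct(evEnd, origin = "1970-01-01", tz = "UTC"))
      logStart <- min(evStart + tmpl$logStartLatencyMinutes * 60, evEnd - 60)
      logStart <- max(logStart, t0)
      logEv[[length(logEv) + 1L]] <-
        data.frame(type = tmpl$eventType,
                   start = as.POSIXct(logStart, origin = "1970-01-01",
                                      tz = "UTC"),
                   end = as.POSIXct(evEnd, origin = "1970-01-01", tz = "UTC"))
    }
  }
  trueEv <- if (length(trueEv)) do.call(rbind, trueEv) else
    data.frame(type = character(),
               start = .asTime(character()), end = .asTime(character()))
  logDf <- if (length(logEv)) do.call(rbind, logEv) else
    data.frame(type = character(),
               start = .asTime(character()), end = .asTime(character()))

  new("SimulatedPatient",
      recorded = ActivitySeries(recorded, startTime, 60L, patientId),
      endogenousTruth = ActivitySeries(endo, startTime, 60L, patientId),
      log = EventLog(type = logDf$type, start = logDf$start, end = logDf$end,
                     patientId = patientId),
      trueEvents = trueEv,
      trueSpec = unclass(spec),
      seed = as.integer(seed))
}

#' Cohort simulation configurations
#'
#' `defaultCohortConfig()` draws UWS-like patients with lower baseline
#' activity and weaker rhythm amplitude than MCS/EMCS-like patients, both
#' entrained to 24 h, under the default care schedule.
#' `headlineBiasConfig()` is the bias-demonstration condition: weak
#' endogenous rhythms free-running at 25 h in both groups, confounded by a
#' strong 24-h care schedule, so that uncorrected recordings look circadian
#' while the corrected ones reveal the non-24-h endogenous period.
#'
#' Parameter ranges are `c(lo, hi)` bounds of per-patient uniform draws.
#'
#' @param periodHours endogenous period used for every patient.
#' @param templates care-event templates shared across patients (all patients
#'   are assumed to receive equivalent care).
#' @return A list with elements `groups` (per-diagnosis-group parameter
#'   ranges) and `templates`, consumable by [generateCohort()].
#' @export
defaultCohortConfig <- function(periodHours = 24,
                                templates = defaultCareTemplates()) {
  list(groups = list(
         UWS = list(mesor = c(6, 12), amplitude = c(2, 5),
                    noiseSd = c(4, 8), periodHours = periodHours,
                    acrophaseHours = 15, crsRange = c(1, 8)),
         MCS_EMCS = list(mesor = c(15, 30), amplitude = c(6, 14),
                         noiseSd = c(6, 12), periodHours = periodHours,
                         acrophaseHours = 15, crsRange = c(8, 23))),
       templates = templates)
}

#' @rdname defaultCohortConfig
#' @export
headlineBiasConfig <- function(periodHours = 25, templates = NULL) {
  if (is.null(templates)) {
    ## "strong 24-h-scheduled care": the same routine every day, near-certain
    ## occurrence, modest jitter, passive activity far above patient baselines
    templates <- list(
      careTemplate("nursing", "06:45", 30, jitterSdMinutes = 8,
                   passiveAmplitude = 100),
      careTemplate("nursing", "12:00", 20, jitterSdMinutes = 8,
                   passiveAmplitude = 100),
      careTemplate("nursing", "19:30", 25, jitterSdMinutes = 8,
                   passiveAmplitude = 100),
      careTemplate("therapy", "10:00", 30, jitterSdMinutes = 12,
                   passiveAmplitude = 100, occurrenceProbability = 0.9),
      careTemplate("visit", "15:00", 60, jitterSdMinutes = 15,
                   passiveAmplitude = 100, occurrenceProbability = 0.9))
  }
  cfg <- defaultCohortConfig(periodHours, templates)
  ## "weak endogenous rhythm": amplitude well below the epoch noise, so the
  ## patient's own 25-h component is faint (though detectable over 7 days)
  cfg$groups$UWS$amplitude <- c(0.5, 1.5)
  cfg$groups$MCS_EMCS$amplitude <- c(1, 2.5)
  cfg$groups$MCS_EMCS$mesor <- c(12, 20)
  cfg$groups$MCS_EMCS$noiseSd <- c(6, 10)
  cfg
}

#' Simulate a ward cohort
#'
#' Draws per-patient rhythm parameters from the per-group ranges in `config`,
#' simulates each patient with [generatePatient()], and assembles a cohort
#' metadata table. Deterministic under `seed`.
#'
#' @param config a configuration from [defaultCohortConfig()] or
#'   [headlineBiasConfig()].
#' @param nPerGroup named integer vector, patients per diagnosis group,
#'   e.g. `c(UWS = 19, MCS_EMCS = 11)`; every group must have at least one
#'   patient.
#' @param days recording length in days.
#' @param seed integer master seed; per-patient seeds are derived from it.
#' @return A list with `patients` (list of [SimulatedPatient-class]) and
#'   `cohort` (data.frame with `patient_id`, `diagnosis`, `diagnosis_group`,
#'   `etiology`, `age`, `gender`, `months_since_injury`, `crs_r_sum`, and the
#'   true rhythm parameters).
#' @export
#' @examples
#' cs <- generateCohort(nPerGroup = c(UWS = 2, MCS_EMCS = 2), days = 2,
#'                      seed = 7)
#' cs$cohort[, c("patient_id", "diagnosis_group", "true_amplitude")]
generateCohort <- function(config = defaultCohortConfig(),
                           nPerGroup = c(UWS = 19, MCS_EMCS = 11),
                           days = 7L, seed = 1L) {
  if (any(nPerGroup < 1L)) stop("every group needs at least one patient")
  if (is.null(names(nPerGroup)) || !all(names(nPerGroup) %in%
                                        names(config$groups)))
    stop("nPerGroup must be named after groups in config$groups")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nTot <- sum(nPerGroup)
  patSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
  patients <- vector("list", nTot)
  rows <- vector("list", nTot)
  k <- 0L
  for (g in names(nPerGroup)) {
    gp <- config$groups[[g]]
    for (j in seq_len(nPerGroup[[g]])) {
      k <- k + 1L
      id <- sprintf("S%02d", k)
      mesor <- stats::runif(1, gp$mesor[1], gp$mesor[2])
      amp <- stats::runif(1, gp$amplitude[1], gp$amplitude[2])
      noiseSd <- stats::runif(1, gp$noiseSd[1], gp$noiseSd[2])
      crs <- sample(seq(gp$crsRange[1], gp$crsRange[2]), 1)
      age <- sample(19:78, 1)
      gender <- sample(c("M", "F"), 1)
      etiology <- sample(c("TBI", "NTBI"), 1, prob = c(0.4, 0.6))
      months <- round(stats::runif(1, 1.5, 200), 1)
      spec <- rhythmSpec(mesor = mesor, amplitude = min(amp, mesor),
                         periodHours = gp$periodHours,
                         acrophaseHours = gp$acrophaseHours,
                         noiseSd = noiseSd)
      patients[[k]] <- generatePatient(spec, config$templates, days = days,
                                       seed = patSeeds[k], patientId = id)
      rows[[k]] <- data.frame(
        patient_id = id,
        diagnosis = if (g == "UWS") "UWS" else "MCS",
        diagnosis_group = g,
        etiology = etiology, age = age, gender = gender,
        months_since_injury = months, crs_r_sum = crs,
        true_mesor = mesor, true_amplitude = min(amp, mesor),
        true_period_hours = gp$periodHours, true_noise_sd = noiseSd,
        seed = patSeeds[k])
    }
  }
  cohort <- do.call(rbind, rows)
  cohort$diagnosis_group <- factor(cohort$diagnosis_group,
                                   levels = c("UWS", "MCS_EMCS"))
  list(patients = patients, cohort = cohort)
}
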
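#' @include stats.R
NULL

.contrastMetrics <- c("is", "iv", "deviation_h", "norm_power",
                      "mean_day", "mean_night")

.trendFlag <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.05, "significant",
                ifelse(p <= 0.1, "trend", "ns")))
}

.pairedRow <- function(metric, label, a, b, sideA, sideB) {
  ok <- stats::complete.cases(a, b)
  nUsable <- sum(ok & a != b)
  base <- data.frame(metric = metric, contrast = label,
                     side_a = sideA, side_b = sideB,
                     median_a = stats::median(a[ok]),
                     median_b = stats::median(b[ok]),
                     n = sum(ok), statistic = NA_real_, z = NA_real_,
                     p = NA_real_, r = NA_real_, effect = NA_character_,
                     flag = NA_character_, computed = FALSE,
                     stringsAsFactors = FALSE)
  if (sum(ok) < 5L || nUsable < 1L) {
    message("contrast '", label, "' for metric '", metric,
            "' not computed (", sum(ok), " usable pairs)")
    return(base)
  }
  tst <- suppressWarnings(wilcoxonSignedRank(a[ok], b[ok],
                                             nEffect = sum(ok)))
  base$statistic <- unname(tst$statistic)
  base$z <- tst$z_value
  base$p <- tst$p.value
  base$r <- tst$effect_size_r
  base$effect <- effectSizeLabel(tst$effect_size_r)
  base$flag <- .trendFlag(tst$p.value)
  base$computed <- !is.na(tst$p.value)
  base
}

.unpairedRow <- function(metric, label, x, y, sideA, sideB) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- data.frame(metric = metric, contrast = label,
                     side_a = sideA, side_b = sideB,
                     median_a = stats::median(x), median_b = stats::median(y),
                     n = length(x) + length(y), statistic = NA_real_,
                     z = NA_real_, p = NA_real_, r = NA_real_,
                     effect = NA_character_, flag = NA_character_,
                     computed = FALSE, stringsAsFactors = FALSE)
  if (length(x) < 3L || length(y) < 3L) {
    message("contrast '", label, "' for metric '", metric,
            "' not computed (groups of ", length(x), " and ", length(y), ")")
    return(base)
  }
  tst <- suppressWarnings(mannWhitneyU(x, y))
  base$statistic <- unname(tst$statistic)
  base$z <- tst$z_value
  base$p <- tst$p.value
  base$r <- tst$effect_size_r
  base$effect <- effectSizeLabel(tst$effect_size_r)
  base$flag <- .trendFlag(tst$p.value)
  base$computed <- !is.na(tst$p.value)
  base
}

#' Cohort-level contrast tables
#'
#' Builds the study's contrast tables from per-patient circadian summaries of
#' the corrected and uncorrected datasets plus the cohort metadata:
#' \enumerate{
#'   \item paired uncorrected-vs-corrected Wilcoxon tests per metric (IS, IV,
#'     deviation from 24 h, normalized power, day and night mean activity);
#'   \item UWS vs MCS/EMCS Mann-Whitney tests per metric, within each dataset;
#'   \item paired day-vs-night activity tests within each dataset, overall
#'     and per diagnosis group;
#'   \item TBI vs NTBI Mann-Whitney tests per metric, within each dataset;
#'   \item Kendall tau-b correlations of the CRS-R sum score (and any
#'     `crs_r_*` subscale columns present) with each metric, on the corrected
#'     dataset.
#' }
#' Patients with an undefined value for a metric are excluded listwise for
#' that metric (with a message). Paired rows with fewer than 5 usable pairs
#' are marked not computed. Effect sizes carry conventional labels
#' (small/medium/large at 0.1/0.3/0.5) and p-values in (0.05, 0.1] are
#' flagged as trends. No multiple-testing correction is applied.
#'
#' @param summaryCorrected,summaryUncorrected per-patient summary tables from
#'   [summarizeCohort()] for the corrected and uncorrected datasets.
#' @param cohort cohort metadata with `patient_id`, `diagnosis_group`,
#'   `etiology`, `crs_r_sum` (e.g. from [loadCohortTable()] or
#'   [generateCohort()]).
#' @return A named list of data.frames: `corrected_vs_uncorrected`,
#'   `diagnosis`, `day_vs_night`, `etiology`, `crs_r`.
#' @export
buildContrastTables <- function(summaryCorrected, summaryUncorrected, cohort) {
  m <- merge(merge(cohort, summaryUncorrected, by = "patient_id"),
             summaryCorrected, by = "patient_id",
             suffixes = c("_unc", "_cor"))
  if (!nrow(m)) stop("no patients shared by the summaries and the cohort")

  paired <- do.call(rbind, lapply(.contrastMetrics, function(met) {
    .pairedRow(met, "uncorrected vs corrected",
               m[[paste0(met, "_unc")]], m[[paste0(met, "_cor")]],
               "uncorrected", "corrected")
  }))

  diag <- do.call(rbind, lapply(c("uncorrected", "corrected"), function(ds) {
    sfx <- if (ds == "corrected") "_cor" else "_unc"
    do.call(rbind, lapply(.contrastMetrics, function(met) {
      v <- m[[paste0(met, sfx)]]
      g2 <- m$diagnosis_group == "MCS_EMCS"
      out <- .unpairedRow(met, paste0("MCS/EMCS vs UWS (", ds, ")"),
                          v[g2], v[!g2], "MCS_EMCS", "UWS")
      out$dataset <- ds
      out
    }))
  }))

  dayNight <- do.call(rbind, lapply(c("uncorrected", "corrected"),
                                    function(ds) {
    sfx <- if (ds == "corrected") "_cor" else "_unc"
    groups <- list(all = rep(TRUE, nrow(m)),
                   UWS = m$diagnosis_group == "UWS",
                   MCS_EMCS = m$diagnosis_group == "MCS_EMCS")
    do.call(rbind, lapply(names(groups), function(g) {
      sel <- groups[[g]]
      out <- .pairedRow("mean_activity",
                        paste0("day vs night, ", g, " (", ds, ")"),
                        m[[paste0("mean_day", sfx)]][sel],
                        m[[paste0("mean_night", sfx)]][sel],
                        "day", "night")
      out$dataset <- ds
      out$group <- g
      out
    }))
  }))

  etio <- do.call(rbind, lapply(c("uncorrected", "corrected"), function(ds) {
    sfx <- if (ds == "corrected") "_cor" else "_unc"
    do.call(rbind, lapply(.contrastMetrics, function(met) {
      v <- m[[paste0(met, sfx)]]
      tbi <- m$etiology == "TBI"
      out <- .unpairedRow(met, paste0("TBI vs NTBI (", ds, ")"),
                          v[tbi], v[!tbi], "TBI", "NTBI")
      out$dataset <- ds
      out
    }))
  }))

  crsCols <- c("crs_r_sum", grep("^crs_r_(?!sum)", names(m), value = TRUE,
                                 perl = TRUE))
  crsCols <- intersect(crsCols, names(m))
  crs <- do.call(rbind, lapply(crsCols, function(cc) {
    do.call(rbind, lapply(.contrastMetrics, function(met) {
      v <- m[[paste0(met, "_cor")]]
      ok <- stats::complete.cases(v, m[[cc]])
      if (sum(ok) < 4L || stats::var(m[[cc]][ok]) == 0 ||
          stats::var(v[ok]) == 0) {
        return(data.frame(crs_scale = cc, metric = met, n = sum(ok),
                          tau = NA_real_, z = NA_real_, p = NA_real_,
                          flag = NA_character_, computed = FALSE,
                          stringsAsFactors = FALSE))
      }
      tst <- suppressWarnings(kendallTau(m[[cc]][ok], v[ok]))
      data.frame(crs_scale = cc, metric = met, n = sum(ok),
                 tau = unname(tst$statistic), z = tst$z_value,
                 p = tst$p.value, flag = .trendFlag(tst$p.value),
                 computed = !is.na(tst$p.value), stringsAsFactors = FALSE)
    }))
  }))

  list(corrected_vs_uncorrected = paired, diagnosis = diag,
       day_vs_night = dayNight, etiology = etio, crs_r = crs)
}
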
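test_that("degenerate spec yields a constant recording", {
  p <- generatePatient(rhythmSpec(mesor = 7, amplitude = 0, noiseSd = 0),
                       templates = list(), days = 2, seed = 1)
  expect_equal(activityValues(p@recorded), rep(7, 2 * 1440))
  expect_equal(activityValues(p@endogenousTruth), activityValues(p@recorded))
  expect_equal(nEvents(p@log), 0L)
})

test_that("generation is deterministic under the seed", {
  spec <- rhythmSpec(10, 4, noiseSd = 3)
  tm <- defaultCareTemplates()
  a <- generatePatient(spec, tm, days = 3, seed = 42)
  b <- generatePatient(spec, tm, days = 3, seed = 42)
  expect_identical(activityValues(a@recorded), activityValues(b@recorded))
  expect_identical(events(a@log), events(b@log))
  c <- generatePatient(spec, tm, days = 3, seed = 43)
  expect_false(identical(activityValues(c@recorded),
                         activityValues(a@recorded)))
})

test_that("care events inject passive activity at the scheduled rate", {
  tmpl <- careTemplate("nursing", "12:00", durationMinutes = 30,
                       jitterSdMinutes = 5, passiveAmplitude = 500,
                       occurrenceProbability = 0.6)
  p <- generatePatient(rhythmSpec(10, 0, noiseSd = 2), list(tmpl),
                       days = 50, seed = 11)
  ev <- p@trueEvents
  # occurrence count concentrates around probability * days
  expect_gt(nrow(ev), 50 * 0.6 - 4 * sqrt(50 * 0.6 * 0.4))
  expect_lt(nrow(ev), 50 * 0.6 + 4 * sqrt(50 * 0.6 * 0.4))

  tt <- epochTimes(p@recorded)
  inside <- rep(FALSE, nEpochs(p@recorded))
  for (i in seq_len(nrow(ev)))
    inside <- inside | (tt >= ev$start[i] & tt < ev$end[i])
  v <- activityValues(p@recorded)
  expect_gt(mean(v[inside]), mean(v[!inside]))
  # recorded dominates truth inside events by the passive amplitude
  expect_true(all(v[inside] - activityValues(p@endogenousTruth)[inside]
                  >= 500 - 1e-9))
  # the log start lags the true start by the configured latency
  lag <- as.numeric(events(p@log)$start - ev$start, units = "mins")
  expect_true(all(abs(lag - 3) < 1e-9))
})

test_that("short recordings and invalid specs are rejected", {
  expect_error(generatePatient(rhythmSpec(5, 1), days = 1, seed = 1),
               "at least two cycles")
  expect_error(rhythmSpec(mesor = 5, amplitude = 9), "exceed mesor")
  expect_error(rhythmSpec(5, 1, periodHours = 60), "periodHours")
  # rhythm_present = FALSE forces a flat mean structure
  sp <- rhythmSpec(5, 4, rhythmPresent = FALSE)
  expect_equal(sp$amplitude, 0)
})

test_that("poisson-like noise yields integer counts dominating the truth", {
  p <- generatePatient(rhythmSpec(6, 3, noiseSd = 0,
                                  noiseFamily = "poisson_like"),
                       defaultCareTemplates(50), days = 2, seed = 5)
  expect_true(all(activityValues(p@endogenousTruth) ==
                  round(activityValues(p@endogenousTruth))))
  expect_true(all(activityValues(p@recorded) >=
                  activityValues(p@endogenousTruth)))
})

test_that("cohort generation respects group structure", {
  cs <- generateCohort(nPerGroup = c(UWS = 3, MCS_EMCS = 3), days = 2,
                       seed = 7)
  expect_length(cs$patients, 6L)
  expect_equal(as.character(cs$cohort$diagnosis_group),
               rep(c("UWS", "MCS_EMCS"), each = 3))
  expect_gt(mean(cs$cohort$true_amplitude[cs$cohort$diagnosis_group ==
                                          "MCS_EMCS"]),
            mean(cs$cohort$true_amplitude[cs$cohort$diagnosis_group ==
                                          "UWS"]))
  expect_error(generateCohort(nPerGroup = c(UWS = 0, MCS_EMCS = 3)),
               "at least one")

  # different master seeds change realizations, not the schedule itself
  cs2 <- generateCohort(nPerGroup = c(UWS = 3, MCS_EMCS = 3), days = 2,
                        seed = 8)
  expect_false(identical(events(cs$patients[[1]]@log),
                         events(cs2$patients[[1]]@log)))
  same <- generateCohort(nPerGroup = c(UWS = 3, MCS_EMCS = 3), days = 2,
                         seed = 7)
  expect_identical(activityValues(same$patients[[4]]@recorded),
                   activityValues(cs$patients[[4]]@recorded))
})

test_that("arrhythmic patients are classified non-circadian almost surely", {
  nonCirc <- 0L
  for (seed in 1:100) {
    p <- generatePatient(rhythmSpec(100, 0, noiseSd = 10,
                                    rhythmPresent = FALSE),
                         templates = list(), days = 2, seed = seed)
    pk <- extractCircadianPeak(lombScargle(p@recorded,
                                           periodRangeHours = c(3, 47)))
    nonCirc <- nonCirc + !pk$is_circadian
  }
  expect_gte(nonCirc / 100, 0.95)
})
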
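test_that("downsampling sums raw values into minutes", {
  raw <- ActivitySeries(rep(1, 60), T0, epochSeconds = 2L)
  m <- downsampleToMinutes(raw)
  expect_equal(activityValues(m), c(30, 30))
  expect_equal(epochSeconds(m), 60L)

  ramp <- ActivitySeries(1:60, T0, epochSeconds = 1L)
  expect_equal(activityValues(downsampleToMinutes(ramp)), 1830)

  zero <- ActivitySeries(rep(0, 180), T0, epochSeconds = 1L)
  expect_equal(activityValues(downsampleToMinutes(zero)), rep(0, 3))

  # trailing partial minute dropped; mean aggregator available
  raw2 <- ActivitySeries(rep(2, 70), T0, epochSeconds = 2L)
  expect_equal(activityValues(downsampleToMinutes(raw2)), rep(60, 2))
  expect_equal(activityValues(downsampleToMinutes(raw2, "mean")), rep(2, 2))

  expect_error(downsampleToMinutes(constantSeries(1, 10)), "already")
})

test_that("removal intervals get type-specific pads and merge", {
  s <- constantSeries(1, 1440)
  iv <- buildRemovalIntervals(eventAt("nursing", "2020-01-06T10:00:00",
                                      "2020-01-06T10:20:00"),
                              defaultPaddingPolicy(), s)
  expect_equal(nrow(iv), 1L)
  expect_equal(format(iv$start, "%H:%M"), "09:55")
  expect_equal(format(iv$end, "%H:%M"), "10:25")

  log <- EventLog(type = c("visit", "wheelchair"),
                  start = c("2020-01-06T14:00:00", "2020-01-06T14:50:00"),
                  end = c("2020-01-06T15:00:00", "2020-01-06T15:30:00"))
  iv <- buildRemovalIntervals(log, defaultPaddingPolicy(), s)
  expect_equal(nrow(iv), 1L)
  expect_equal(format(iv$start, "%H:%M"), "13:50")
  expect_equal(format(iv$end, "%H:%M"), "15:40")
  expect_equal(iv$source_types, "visit;wheelchair")

  # point events never cause removal; out-of-span events are skipped
  expect_equal(nrow(buildRemovalIntervals(
    eventAt("medication", "2020-01-06T08:00:00"),
    defaultPaddingPolicy(), s)), 0L)
  expect_message(
    iv <- buildRemovalIntervals(eventAt("visit", "2020-01-08T10:00:00",
                                        "2020-01-08T11:00:00"),
                                defaultPaddingPolicy(), s),
    "outside")
  expect_equal(nrow(iv), 0L)
})

test_that("two-sided median imputation follows the half/half rule", {
  s <- ActivitySeries(c(seq(2, 20, by = 2), 0, 0, 0, 0, rep(100, 10)), T0)
  imp <- imputeInterval(s, c(11, 14))
  expect_equal(imp$values, c(11, 11, 100, 100))
  expect_equal(imp$from, c("before", "before", "after", "after"))

  # odd length: the preceding median gets the extra epoch
  s2 <- ActivitySeries(c(rep(1, 10), 0, 0, 0, rep(9, 10)), T0)
  imp2 <- imputeInterval(s2, c(11, 13))
  expect_equal(imp2$values, c(1, 1, 9))

  # boundary interval falls back to the available side
  s3 <- ActivitySeries(c(0, 0, rep(7, 10)), T0)
  imp3 <- imputeInterval(s3, c(1, 2))
  expect_equal(imp3$values, c(7, 7))
  expect_equal(imp3$from, c("after", "after"))

  expect_error(imputeInterval(constantSeries(3, 10), c(1, 10)),
               "uncorrectable")
})

test_that("imputation context skips neighbouring removal intervals", {
  # interval A (epochs 6..10) sits right before interval B (11..15);
  # context for B must skip A's epochs and use 1..5 instead.
  v <- c(rep(4, 5), rep(50, 5), rep(60, 5), rep(8, 5))
  s <- ActivitySeries(v, T0)
  removed <- rep(FALSE, 20); removed[6:15] <- TRUE
  impB <- imputeInterval(s, c(11, 15), contextMinutes = 5, removedMask = removed)
  expect_equal(impB$values, c(4, 4, 4, 8, 8))
})

test_that("correction is identity on empty logs and constant series", {
  s <- constantSeries(5, 2880)
  cs <- correctSeries(s, EventLog())
  expect_equal(activityValues(cs), activityValues(s))
  expect_equal(removedFraction(cs), 0)
  expect_true(all(removalMask(cs) == "observed"))

  log <- eventAt("visit", "2020-01-06T10:00:00", "2020-01-06T12:00:00")
  csc <- correctSeries(s, log)
  expect_equal(activityValues(csc), activityValues(s))
  expect_gt(removedFraction(csc), 0)
})

test_that("correction is idempotent and conserves the mask", {
  set.seed(3)
  p <- generatePatient(rhythmSpec(10, 4, noiseSd = 4),
                       defaultCareTemplates(), days = 3, seed = 21)
  cs <- correctSeries(p@recorded, p@log)
  expect_equal(sum(removalMask(cs) == "observed") +
               sum(removalMask(cs) == "removed_imputed"), nEpochs(cs))
  again <- correctSeries(cs, p@log)
  expect_equal(activityValues(again), activityValues(cs))
  expect_identical(removalMask(again), removalMask(cs))

  # imputed values stay inside the range of observed (context) activity
  obs <- activityValues(p@recorded)[removalMask(cs) == "observed"]
  imp <- activityValues(cs)[removalMask(cs) == "removed_imputed"]
  expect_true(all(imp >= min(obs) & imp <= max(obs)))
})

test_that("the mask covers the generator's padded true event windows", {
  # nursing/visit pads (5/10 min) exceed the 3-min logging latency, so every
  # epoch inside a true event window must be removed.
  tmpl <- list(careTemplate("nursing", "09:00", 25, passiveAmplitude = 300),
               careTemplate("visit", "15:00", 45, passiveAmplitude = 300))
  p <- generatePatient(rhythmSpec(10, 3, noiseSd = 3), tmpl, days = 4,
                       seed = 13)
  cs <- correctSeries(p@recorded, p@log)
  tt <- epochTimes(p@recorded)
  inside <- rep(FALSE, nEpochs(p@recorded))
  for (i in seq_len(nrow(p@trueEvents)))
    inside <- inside | (tt >= p@trueEvents$start[i] &
                        tt < p@trueEvents$end[i])
  expect_true(all(removalMask(cs)[inside] == "removed_imputed"))
})

test_that("recordings dominated by events are uncorrectable", {
  s <- constantSeries(2, 1440)
  log <- eventAt("visit", "2020-01-06T00:00:00", "2020-01-07T00:00:00")
  expect_error(correctSeries(s, log), "uncorrectable")
  # above the warning threshold but below the error one
  log2 <- eventAt("visit", "2020-01-06T00:00:00", "2020-01-06T15:00:00")
  expect_warning(correctSeries(s, log2), "caution")
})

test_that("removal accounting scales with event duration", {
  fracs <- vapply(c(10, 30, 60), function(dur) {
    tmpl <- list(careTemplate("nursing", "10:00", dur, jitterSdMinutes = 0,
                              passiveAmplitude = 100))
    p <- generatePatient(rhythmSpec(10, 3, noiseSd = 2), tmpl, days = 3,
                         seed = 9)
    removedFraction(correctSeries(p@recorded, p@log))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))

  s <- constantSeries(1, 1440)
  cs0 <- correctSeries(s, EventLog())
  expect_equal(removedFractionReport(cs0)$overall, 0)
  # exactly half the epochs removed (therapy has no padding)
  cs5 <- correctSeries(s, eventAt("therapy", "2020-01-06T00:00:00",
                                  "2020-01-06T12:00:00"))
  rep5 <- removedFractionReport(cs5)
  expect_equal(rep5$overall, 0.5)
  expect_equal(unname(rep5$perType["therapy"]), 0.5)
  expect_equal(unname(rep5$perType["visit"]), 0)
})

test_that("manual extra intervals merge into the removal set", {
  s <- constantSeries(4, 1440)
  cs <- correctSeries(s, EventLog(),
                      extraIntervals = data.frame(
                        start = "2020-01-06T05:00:00",
                        end = "2020-01-06T06:00:00"))
  expect_equal(sum(removalMask(cs) == "removed_imputed"), 60L)
  expect_equal(removalIntervals(cs)$source_types, "manual")
})

test_that("correction recovers the endogenous period and stability", {
  # weak 25-h rhythm under a 24-h care schedule: the corrected series' peak
  # must sit closer to 25 h, and its IS closer to the endogenous truth, than
  # the uncorrected series' (medians over 20 seeds)
  tmpl <- headlineBiasConfig()$templates
  devU <- devC <- isErrU <- isErrC <- numeric(20)
  for (i in 1:20) {
    p <- generatePatient(rhythmSpec(10, 1.5, periodHours = 25, noiseSd = 6),
                         tmpl, days = 7, seed = 300 + i)
    cs <- suppressWarnings(correctSeries(p@recorded, p@log))
    pkU <- extractCircadianPeak(lombScargle(p@recorded,
                                            periodRangeHours = c(20, 30)))
    pkC <- extractCircadianPeak(lombScargle(cs,
                                            periodRangeHours = c(20, 30)))
    devU[i] <- abs(pkU$period_hours - 25)
    devC[i] <- abs(pkC$period_hours - 25)
    isTruth <- interdailyStability(p@endogenousTruth)
    isErrU[i] <- abs(interdailyStability(p@recorded) - isTruth)
    isErrC[i] <- abs(interdailyStability(cs) - isTruth)
  }
  expect_lt(median(devC, na.rm = TRUE), median(devU, na.rm = TRUE))
  expect_lt(median(isErrC), median(isErrU))
})
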
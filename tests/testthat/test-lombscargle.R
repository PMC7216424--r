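makePg <- function(periods, power, pvals, alpha = 0.001) {
  new("Periodogram", periodsHours = periods, power = power, pValues = pvals,
      ofac = 1, alpha = alpha, nIndepFreq = length(periods),
      nUsed = length(periods))
}

test_that("a planted 24-h sine is recovered within one grid step", {
  set.seed(10)
  s <- sineSeries(days = 7, periodHours = 24, amplitude = 10, noiseSd = 5)
  pg <- lombScargle(s, periodRangeHours = c(3, 48))
  pk <- extractCircadianPeak(pg)
  gridStep <- 24^2 / (100 * 168)   # dP = P^2 * df at 24 h
  expect_true(pk$significant)
  expect_lt(abs(pk$period_hours - 24), gridStep + 1e-9)
  expect_lt(pk$p_value, 0.001)
  expect_true(pk$is_circadian)
})

test_that("a planted 25-h sine is recovered within one grid step", {
  set.seed(11)
  s <- sineSeries(days = 7, periodHours = 25, amplitude = 10, noiseSd = 5)
  pk <- extractCircadianPeak(lombScargle(s, periodRangeHours = c(3, 48)))
  gridStep <- 25^2 / (100 * 168)
  expect_lt(abs(pk$period_hours - 25), gridStep + 1e-9)
  expect_lt(pk$p_value, 0.001)
  expect_equal(pk$deviation_from_24h, abs(pk$period_hours - 24))
})

test_that("peak selection follows the closest-to-24 h rule", {
  # two significant peaks: 12.0 h and 23.5 h -> pick 23.5, circadian
  periods <- seq(30, 10, by = -0.5)
  power <- rep(1, length(periods))
  power[periods == 23.5] <- 50
  power[periods == 12] <- 80
  pvals <- rep(0.5, length(periods))
  pvals[power > 10] <- 1e-6
  pk <- extractCircadianPeak(makePg(periods, power, pvals))
  expect_equal(pk$period_hours, 23.5)
  expect_equal(pk$deviation_from_24h, 0.5)
  expect_true(pk$is_circadian)

  # single significant peak at 22.5 h -> deviation 1.5, not circadian
  power2 <- rep(1, length(periods)); pvals2 <- rep(0.5, length(periods))
  power2[periods == 22.5] <- 60; pvals2[periods == 22.5] <- 1e-6
  pk2 <- extractCircadianPeak(makePg(periods, power2, pvals2))
  expect_equal(pk2$period_hours, 22.5)
  expect_equal(pk2$deviation_from_24h, 1.5)
  expect_false(pk2$is_circadian)

  # no significant peak -> not circadian, period undefined
  pk3 <- extractCircadianPeak(makePg(periods, power, rep(0.5,
                                                         length(periods))))
  expect_false(pk3$significant)
  expect_false(pk3$is_circadian)
  expect_true(is.na(pk3$period_hours))
})

test_that("peak extraction matches a brute-force scan on small grids", {
  set.seed(12)
  for (rep in 1:20) {
    k <- 40
    periods <- seq(36, 6, length.out = k)
    power <- abs(cumsum(rnorm(k)))
    pvals <- exp(-power)
    pg <- makePg(periods, power, pvals, alpha = 0.4)
    # oracle: all strict local maxima with p < alpha, closest to 24
    cand <- which(power[2:(k - 1)] > power[1:(k - 2)] &
                  power[2:(k - 1)] > power[3:k]) + 1
    cand <- cand[pvals[cand] < 0.4]
    pk <- extractCircadianPeak(pg)
    if (!length(cand)) {
      expect_false(pk$significant)
    } else {
      best <- cand[which.min(abs(periods[cand] - 24))]
      expect_equal(pk$period_hours, periods[best])
      expect_equal(pk$normalized_power_at_peak, power[best])
    }
  }
})

test_that("white noise rarely produces a significant peak at alpha = 0.001", {
  set.seed(13)
  hits <- 0L
  for (i in 1:200) {
    s <- noiseSeries(288, epochSeconds = 600L)   # 2 days at 10-min epochs
    pg <- lombScargle(s, periodRangeHours = c(3, 47))
    hits <- hits + any(pg@pValues < 0.001)
  }
  expect_lte(hits / 200, 0.02)
})

test_that("power at the true period grows with endogenous amplitude", {
  set.seed(14)
  ladder <- c(1, 2, 4, 6, 8)
  for (i in 1:50) {
    noise <- rnorm(288, 0, 1)
    h <- (0:287) / 6
    pow <- vapply(ladder, function(a) {
      y <- pmax(20 + a * cos(2 * pi * (h - 15) / 24) + noise, 0)
      pg <- lombScargle(h, values = y, periodRangeHours = c(20, 30))
      pg@power[which.min(abs(pg@periodsHours - 24))]
    }, numeric(1))
    expect_true(all(diff(pow) > 0))
  }
})

test_that("LS power is invariant to positive affine rescaling", {
  set.seed(15)
  s <- sineSeries(days = 3, noiseSd = 4)
  s2 <- ActivitySeries(2.5 * activityValues(s) + 7, startTime(s),
                       epochSeconds(s))
  p1 <- lombScargle(s, periodRangeHours = c(20, 30))
  p2 <- lombScargle(s2, periodRangeHours = c(20, 30))
  expect_equal(p2@power, p1@power, tolerance = 1e-9)
})

test_that("degenerate inputs signal undefined results", {
  expect_warning(pg <- lombScargle(constantSeries(5, 100)), "constant")
  expect_length(pg@power, 0L)
  expect_false(extractCircadianPeak(pg)$significant)
  expect_error(lombScargle(c(0, 1), values = c(1, 2)), "3 distinct")
})
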
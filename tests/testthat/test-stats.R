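test_that("signed-rank test matches the exhaustive sign-flip oracle", {
  set.seed(20)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    a <- round(rnorm(n, 0, 4), 1)
    b <- round(rnorm(n, 0.8, 4), 1)
    if (all(a == b)) next
    pExact <- suppressWarnings(wilcoxonSignedRank(a, b,
                                                  mode = "exact")$p.value)
    expect_equal(pExact, bruteSignedRankP(a, b), tolerance = 1e-12)
    # the normal approximation is close to the exact law at these sizes
    pNorm <- suppressWarnings(wilcoxonSignedRank(a, b)$p.value)
    expect_lt(abs(pNorm - pExact), 0.12)
  }
})

test_that("signed-rank normal approximation matches the reference
           implementation", {
  set.seed(21)
  a <- round(rnorm(15, 0, 3), 0)
  b <- round(rnorm(15, 1, 3), 0)   # integers force ties
  ours <- suppressWarnings(wilcoxonSignedRank(a, b))
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("all-zero differences give an undefined signed-rank result", {
  expect_warning(res <- wilcoxonSignedRank(1:6, 1:6), "zero")
  expect_true(is.na(res$p.value))
  expect_true(is.na(res$z_value))
})

test_that("Mann-Whitney U matches brute-force pairwise wins and the
           enumeration oracle", {
  x <- c(1.2, 3.5, 7.1, 9.4)
  y <- c(0.8, 2.2, 3.5, 5.0, 6.3)
  res <- mannWhitneyU(x, y)
  wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(res$statistic), wins)

  set.seed(22)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- round(rnorm(n1, 0, 3), 0)
    y <- round(rnorm(n2, 1, 3), 0)
    oracle <- bruteMannWhitney(x, y)
    exact <- mannWhitneyU(x, y, mode = "exact")
    expect_equal(unname(exact$statistic), oracle$U)
    expect_equal(exact$p.value, oracle$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with the reference normal approximation", {
  set.seed(23)
  x <- round(rnorm(12, 0, 3), 0)
  y <- round(rnorm(15, 1, 3), 0)
  ours <- mannWhitneyU(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("identical groups give p ~ 1 and r ~ 0", {
  res <- mannWhitneyU(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(res$p.value, 1)
  expect_equal(res$effect_size_r, 0)
})

test_that("Kendall tau handles monotone maps, reversals and ties", {
  expect_equal(unname(kendallTau(1:6, exp(1:6))$statistic), 1)
  expect_equal(unname(kendallTau(1:6, -(1:6))$statistic), -1)
  set.seed(24)
  for (i in 1:5) {
    x <- sample(1:4, 6, replace = TRUE)
    y <- sample(1:4, 6, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(unname(kendallTau(x, y)$statistic), bruteTauB(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(res <- kendallTau(rep(2, 6), 1:6), "constant")
  expect_true(is.na(res$p.value))
})

test_that("effect size r reproduces the |Z|/sqrt(N) convention", {
  expect_equal(effectSizeR(0, 29), 0)
  expect_equal(round(effectSizeR(-4.22, 29), 2), 0.78)
  expect_equal(round(effectSizeR(-2.89, 11), 2), 0.87)
  expect_equal(effectSizeR(2.5, 25), effectSizeR(-2.5, 25))
  expect_error(effectSizeR(1, 0), "positive")
  expect_equal(effectSizeLabel(c(0.05, 0.15, 0.35, 0.55)),
               c("negligible", "small", "medium", "large"))
})

test_that("rank tests are invariant to adding a constant", {
  set.seed(25)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  r1 <- suppressWarnings(wilcoxonSignedRank(a, b))
  r2 <- suppressWarnings(wilcoxonSignedRank(a + 100, b + 100))
  expect_equal(r2$p.value, r1$p.value)
  expect_equal(r2$z_value, r1$z_value)
  m1 <- mannWhitneyU(a, b)
  m2 <- mannWhitneyU(a + 100, b + 100)
  expect_equal(m2$p.value, m1$p.value)
})
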
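#' @include AllClasses.R
NULL

.testResult <- function(method, statistic, z, p, r, n, dataName = "") {
  structure(list(statistic = statistic, z_value = z, p.value = p,
                 effect_size_r = r, n = n, method = method,
                 alternative = "two.sided", data.name = dataName),
            class = c("wardTest", "htest"))
}

.undefinedTest <- function(method, n, why) {
  warning(method, " undefined: ", why, call. = FALSE)
  .testResult(method, c(statistic = NA_real_), NA_real_, NA_real_, NA_real_, n)
}

#' Wilcoxon signed-rank test with Z and effect size
#'
#' Two-sided paired test. Zero differences are dropped (the standard
#' convention), |differences| are ranked with mid-ranks for ties, and the
#' default Z comes from the tie-corrected normal approximation without
#' continuity correction. The effect size `r = |Z|/sqrt(N)` uses `nEffect`,
#' by default the number of pairs entering the test before zero differences
#' are dropped (the whole-cohort N convention). `mode = "exact"` computes the
#' two-sided p by exhaustive enumeration of all sign assignments (feasible up
#' to ~16 nonzero pairs), defined as the probability of a signed-rank sum at
#' least as far from its mean as observed.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param mode `"normal"` (default) or `"exact"`.
#' @param nEffect denominator N for the effect size.
#' @return An `htest`-like object with `statistic` (V, the positive-rank
#'   sum), `z_value`, `p.value`, `effect_size_r` and `n` (nonzero pairs).
#'   If all differences are zero the result carries `NA`s and a warning is
#'   issued.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(12); b <- a + rnorm(12, 0.8)
#' wilcoxonSignedRank(a, b)
wilcoxonSignedRank <- function(a, b, mode = c("normal", "exact"),
                               nEffect = length(a)) {
  mode <- match.arg(mode)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L)
    return(.undefinedTest("Wilcoxon signed-rank test", 0L,
                          "all paired differences are zero"))
  if (n < 5L)
    warning("fewer than 5 nonzero pairs; the test has little power",
            call. = FALSE)
  rk <- rank(abs(nz))
  V <- sum(rk[nz > 0])
  mu <- n * (n + 1) / 4
  tieTab <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
  z <- if (sig2 > 0) (V - mu) / sqrt(sig2) else NA_real_
  if (mode == "exact") {
    if (n > 16L) stop("exact mode limited to 16 nonzero pairs")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vperm <- as.numeric(signs %*% rk)
    p <- mean(abs(Vperm - mu) >= abs(V - mu) - 1e-9)
  } else {
    p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  }
  .testResult("Wilcoxon signed-rank test", c(V = V), z,
              min(p, 1), if (is.na(z)) NA_real_ else effectSizeR(z, nEffect),
              n, paste(deparse(substitute(a)), "vs", deparse(substitute(b))))
}

#' Mann-Whitney U test with Z and effect size
#'
#' Two-sided unpaired rank test; Z from the tie-corrected normal
#' approximation without continuity correction, effect size
#' `r = |Z|/sqrt(n1 + n2)`. `mode = "exact"` enumerates all assignments of
#' the pooled ranks to the first group (feasible while `choose(n1+n2, n1)` is
#' small) and computes the two-sided p as the probability of a U at least as
#' far from its mean as observed.
#'
#' @param x,y numeric vectors for the two groups.
#' @param mode `"normal"` (default) or `"exact"`.
#' @return An `htest`-like object with `statistic` (U for the first group),
#'   `z_value`, `p.value`, `effect_size_r` and `n = c(n1, n2)`.
#' @export
#' @examples
#' mannWhitneyU(c(1, 5, 8, 9), c(2, 3, 4, 6, 7))
mannWhitneyU <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  n <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tieTab <- table(rk)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else NA_real_
  if (mode == "exact") {
    if (choose(n, n1) > 2e5) stop("exact mode infeasible for these sizes")
    combs <- utils::combn(n, n1)
    Uperm <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
  } else {
    p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  }
  .testResult("Mann-Whitney U test", c(U = U), z, min(p, 1),
              if (is.na(z)) NA_real_ else effectSizeR(z, n), c(n1 = n1, n2 = n2),
              paste(deparse(substitute(x)), "vs", deparse(substitute(y))))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a two-sided p-value from the normal
#' approximation (appropriate for heavily tied ordinal scores such as CRS-R).
#' Delegates to [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @return An `htest`-like object with `statistic` (tau-b), `z_value`,
#'   `p.value` and `n`. Constant input on either side yields an `NA` result
#'   with a warning.
#' @export
#' @examples
#' kendallTau(1:6, c(2, 2, 3, 5, 5, 8))
kendallTau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("kendallTau needs at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(.undefinedTest("Kendall rank correlation", n,
                          "one variable is constant"))
  ct <- stats::cor.test(x, y, method = "kendall", exact = FALSE)
  z <- unname(ct$statistic)
  .testResult("Kendall rank correlation", c(tau = unname(ct$estimate)),
              z, ct$p.value, effectSizeR(z, n), n)
}

#' Effect size r for rank-based tests
#'
#' `r = |Z| / sqrt(N)`, with N the total number of observations entering the
#' contrast. Conventional interpretation thresholds: small 0.1, medium 0.3,
#' large 0.5 (see [effectSizeLabel()]).
#'
#' @param z Z value of the test.
#' @param nTotal total sample size (>= 1).
#' @return Nonnegative numeric.
#' @export
#' @examples
#' effectSizeR(-2.96, 29)   # 0.55 at two decimals
effectSizeR <- function(z, nTotal) {
  if (length(nTotal) != 1L || is.na(nTotal) || nTotal < 1)
    stop("nTotal must be a positive integer")
  abs(z) / sqrt(nTotal)
}

#' @rdname effectSizeR
#' @param r effect size value.
#' @export
effectSizeLabel <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r >= 0.5, "large",
                ifelse(r >= 0.3, "medium",
                       ifelse(r >= 0.1, "small", "negligible"))))
}

## Round half away from zero, the convention used in report output.
.round2 <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
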
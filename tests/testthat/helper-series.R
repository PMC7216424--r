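# Fixture builders shared across the suite. All series use the package's
# timezone-naive local-clock convention and start at midnight unless stated.

T0 <- "2020-01-06T00:00:00"

# Sinusoidal activity at `epochMinutes` resolution, peak at `acrophaseHours`.
sineSeries <- function(days = 7, periodHours = 24, amplitude = 10,
                       mesor = 20, epochMinutes = 1, noiseSd = 0,
                       acrophaseHours = 15, startTime = T0, id = "sine") {
  n <- days * 1440 / epochMinutes
  h <- (seq_len(n) - 1) * epochMinutes / 60
  v <- mesor + amplitude * cos(2 * pi * (h - acrophaseHours) / periodHours)
  if (noiseSd > 0) v <- v + rnorm(n, 0, noiseSd)
  ActivitySeries(pmax(v, 0), startTime, epochMinutes * 60L, id)
}

# Positive-mean white noise (truncation at zero is negligible at mean 100).
noiseSeries <- function(n = 168, mean = 100, sd = 10, epochSeconds = 3600L,
                        startTime = T0, id = "noise") {
  ActivitySeries(pmax(rnorm(n, mean, sd), 0), startTime, epochSeconds, id)
}

constantSeries <- function(value = 5, n = 2880, epochSeconds = 60L,
                           startTime = T0, id = "const") {
  ActivitySeries(rep(value, n), startTime, epochSeconds, id)
}

eventAt <- function(type, start, end = NA, id = "log") {
  EventLog(type = type, start = start, end = end, patientId = id)
}

# Brute-force Kendall tau-b from concordant/discordant pair counts.
bruteTauB <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Exhaustive sign-flip null distribution of the positive-rank sum.
bruteSignedRankP <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vperm <- as.numeric(signs %*% rk)
  mean(abs(Vperm - mu) >= abs(V - mu) - 1e-9)
}

# Exhaustive group-assignment null distribution of U.
bruteMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- combn(n, n1)
  Uperm <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  list(U = U, p = mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9))
}
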
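library(data.table)

# Independent brute-force oracles.  These deliberately re-derive each
# statistic from its definition with plain loops, never touching the
# package's implementation path.

# Mann-Kendall S by exhaustive pair enumeration
mk_s_oracle <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[j] - x[i]
      s <- s + (if (d > 0) 1L else if (d < 0) -1L else 0L)
    }
  }
  s
}

# Var(S) by explicit tied-group enumeration
mk_var_oracle <- function(x) {
  n <- length(x)
  tie <- 0
  for (v in unique(x)) {
    q <- sum(x == v)
    if (q >= 2) tie <- tie + q * (q - 1) * (2 * q + 5)
  }
  (n * (n - 1) * (2 * n + 5) - tie) / 18
}

# global bivariate Moran's I by the direct double sum over the dense
# weight matrix, standardizing with the population (1/n) variance
bimoran_oracle <- function(x, y, wmat) {
  n <- length(x)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  total <- 0
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + wmat[i, j] * zy[j]
    total <- total + zx[i] * acc
  }
  total / n
}

# MDA8 by exhaustive scan of every complete 8-hour window ending in the
# day, over the concatenation of the previous-day tail and the day
mda8_oracle <- function(hourly, prev_hours = NULL) {
  frame <- c(prev_hours, hourly)
  n_prev <- length(prev_hours)
  best <- -Inf
  for (end_hour in 1:24) {              # window ends at this day hour
    start <- end_hour + n_prev - 7L
    if (start < 1) next
    w <- frame[start:(start + 7L)]
    if (sum(!is.na(w)) >= 6) best <- max(best, mean(w, na.rm = TRUE))
  }
  if (is.finite(best)) best else NA_real_
}

# weighted Pearson from the definition
weighted_pearson_oracle <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  num <- sum(w * (x - mx) * (y - my))
  num / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# random series with tied values (rounding forces ties)
random_tied_series <- function(n, digits = 1) {
  round(rnorm(n, sd = 2), digits)
}

# small fast synthetic config for structural tests
tiny_synth <- function(n_cities = 12, seed = 42, ...) {
  synth_config(n_cities = n_cities, seed = seed,
               start_date = "2019-01-01", end_date = "2020-12-31", ...)
}

# noise-free, gap-free world for exact recovery
noise_free_synth <- function(n_cities = 120, seed = 7) {
  synth_config(n_cities = n_cities, seed = seed, noise_sd = 0,
               missing_rate = 0, outlier_rate = 0)
}
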
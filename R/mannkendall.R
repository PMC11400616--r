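## Mann-Kendall trend test with tie-corrected variance

#' Mann-Kendall S statistic
#'
#' `S = sum_{i<j} sgn(x_j - x_i)` over a temporally ordered series.
#'
#' @param x numeric vector in temporal order, finite, length >= 2.
#' @return integer-valued S.
#' @export
mk_s <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("x contains non-finite values; drop invalid periods first",
         call. = FALSE)
  }
  d <- sign(outer(x, x, "-"))      # d[i, j] = sgn(x_i - x_j)
  sum(d[lower.tri(d)])             # rows i > cols j: sgn(x_j' - x_i') pairs
}

#' Tie-corrected variance of the Mann-Kendall S statistic
#'
#' `Var(S) = [n(n-1)(2n+5) - sum_k q_k(q_k-1)(2q_k+5)] / 18`, the sum
#' running over tied groups of size `q_k >= 2`.
#'
#' @inheritParams mk_s
#' @return variance of S.
#' @export
mk_var <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("x contains non-finite values; drop invalid periods first",
         call. = FALSE)
  }
  q <- as.integer(table(x))
  q <- q[q >= 2L]
  (n * (n - 1) * (2 * n + 5) - sum(q * (q - 1) * (2 * q + 5))) / 18
}

#' Continuity-corrected standardized Mann-Kendall Z
#'
#' `Z = (S - 1)/sqrt(Var(S))` for `S > 0`, `0` for `S = 0`,
#' `(S + 1)/sqrt(Var(S))` for `S < 0`.  A zero variance (all values tied)
#' yields `Z = 0` with direction `none`.
#'
#' @param S Mann-Kendall S.
#' @param var_S its variance.
#' @param n series length (the normal approximation assumes `n > 10`; a
#'   smaller `n` is allowed with a warning).
#' @param sig_thresholds named two-sided |Z| thresholds for the 90/95/99%
#'   tiers; defaults are the standard normal critical values.
#' @return list of class `mk_result`: `n`, `S`, `var_S`, `Z`,
#'   `direction` (`increasing`/`decreasing`/`none`) and `sig_tier`
#'   (0, 90, 95 or 99).
#' @export
mk_z <- function(S, var_S, n, sig_thresholds = mk_critical_values()) {
  if (n <= 10) {
    warning("normal approximation is intended for n > 10 (n = ", n, ")",
            call. = FALSE)
  }
  if (var_S < 0) stop("negative variance", call. = FALSE)
  Z <- if (S == 0 || var_S == 0) {
    0
  } else if (S > 0) {
    (S - 1) / sqrt(var_S)
  } else {
    (S + 1) / sqrt(var_S)
  }
  direction <- if (Z > 0) "increasing" else if (Z < 0) "decreasing" else "none"
  tier <- 0L
  for (lev in c(90L, 95L, 99L)) {
    if (abs(Z) >= sig_thresholds[[as.character(lev)]]) tier <- lev
  }
  structure(list(n = n, S = S, var_S = var_S, Z = Z, direction = direction,
                 sig_tier = tier),
            class = "mk_result")
}

#' Two-sided standard normal critical values for the 90/95/99% tiers
#' @param levels confidence levels.
#' @return named numeric vector of `qnorm(1 - (1 - level)/2)`.
#' @export
mk_critical_values <- function(levels = c(0.90, 0.95, 0.99)) {
  out <- qnorm(1 - (1 - levels) / 2)
  names(out) <- as.character(round(levels * 100))
  out
}

#' Mann-Kendall trend test on an ordered series
#'
#' @inheritParams mk_s
#' @param ... passed to [mk_z()].
#' @return an `mk_result` (see [mk_z()]).
#' @export
mann_kendall <- function(x, ...) {
  mk_z(mk_s(x), mk_var(x), length(x), ...)
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall: n = %d, S = %d, Var(S) = %.2f, Z = %.3f (%s%s)\n",
    x$n, as.integer(x$S), x$var_S, x$Z, x$direction,
    if (x$sig_tier > 0) sprintf(", %d%% tier", x$sig_tier) else ""))
  invisible(x)
}

#' Mann-Kendall trends per city and pollutant
#'
#' Runs the test on the valid monthly (default), annual or daily mean
#' series of each city-pollutant; missing periods are dropped (the test is
#' rank-based and tolerates gaps).
#'
#' @param agg output of [aggregate_series()].
#' @param resolution `"monthly"`, `"annual"` or `"daily"` input series.
#' @param series daily series, required for `resolution = "daily"`.
#' @param min_n minimum series length; shorter series are skipped.
#' @return `data.table` (`city_id`, `pollutant`, `n`, `S`, `var_S`, `Z`,
#'   `direction`, `sig_tier`).
#' @export
mk_trends <- function(agg, resolution = c("monthly", "annual", "daily"),
                      series = NULL, min_n = 4L) {
  resolution <- match.arg(resolution)
  src <- switch(resolution,
    monthly = agg$monthly[is_valid == TRUE][order(year, month)],
    annual = agg$annual[is_valid == TRUE][order(year)],
    daily = {
      if (is.null(series)) stop("daily resolution needs the series",
                                call. = FALSE)
      s <- data.table::as.data.table(series)[valid == TRUE][order(date)]
      s[, mean := value]
      s
    })
  src[, {
    x <- mean
    if (length(x) < min_n) {
      NULL  # group dropped, too short
    } else {
      r <- suppressWarnings(mann_kendall(x))
      list(n = r$n, S = r$S, var_S = r$var_S, Z = r$Z,
           direction = r$direction, sig_tier = r$sig_tier)
    }
  }, by = .(city_id, pollutant)]
}
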
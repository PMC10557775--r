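#' Single-component cosinor fit with fixed period
#'
#' Fits `y = M + beta * cos(omega * t) + gamma * sin(omega * t)` by ordinary
#' least squares, with `omega = 2 * pi / period`, and re-expresses the rhythm
#' coefficients as an amplitude `A = sqrt(beta^2 + gamma^2)` and a peak hour
#' (acrophase) `t_peak = atan2(gamma, beta) / omega` wrapped into
#' `[0, period)`. `M` is the MESOR (Midline Estimating Statistic Of Rhythm),
#' the rhythm-adjusted mean. Rhythmicity is assessed by the F-test of the
#' joint null `beta = gamma = 0` against the intercept-only model.
#'
#' @param times Numeric vector of observation times in hours (any origin;
#'   only time modulo the period matters for the fit).
#' @param values Numeric vector of measurements, same length as `times`.
#' @param period Fixed rhythm period in hours (default 24).
#' @return An object of class `cosinor_fit`: a list with elements `mesor`,
#'   `amplitude`, `peak_hour`, `beta`, `gamma`, `residual_sd`, `p_rhythm`,
#'   `n_obs`, `period`, standard errors (`se`), and the model frame
#'   (`data`). Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @details At least 4 observations covering at least 3 distinct times modulo
#'   the period are required; otherwise the three-parameter fit is
#'   underdetermined and an error is raised. A constant series returns
#'   `amplitude = 0` and `p_rhythm = 1`.
#' @examples
#' t <- seq(32, 58, by = 2)
#' y <- 2 + cos(2 * pi * (t - 8) / 24)
#' fit <- cosinor_fit(t, y)
#' tidy(fit)
#' @export
cosinor_fit <- function(times, values, period = 24) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) {
    abort("`times` and `values` must have the same length.")
  }
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]
  values <- values[keep]
  n <- length(values)
  if (n < 4) {
    abort("cosinor_fit() needs at least 4 finite observations.")
  }
  tmod <- round(times %% period, 9)
  if (length(unique(tmod)) < 3) {
    abort(paste0(
      "Degenerate design: fewer than 3 distinct times modulo the period (",
      period, " h); the cosinor fit is underdetermined."
    ))
  }

  if (var(values) == 0) {
    out <- list(
      mesor = values[[1]], amplitude = 0, peak_hour = 0,
      beta = 0, gamma = 0, residual_sd = 0, p_rhythm = 1, n_obs = n,
      period = period,
      se = c(mesor = 0, amplitude = NA_real_, peak_hour = NA_real_),
      data = tibble::tibble(time = times, value = values, fitted = values)
    )
    class(out) <- "cosinor_fit"
    return(out)
  }

  w <- .omega(period)
  X <- cbind(intercept = 1, cosw = cos(w * times), sinw = sin(w * times))
  fit <- stats::lm.fit(X, values)
  co <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sse0 <- sum((values - mean(values))^2)
  df2 <- n - 3
  s2 <- sse / df2
  fstat <- ((sse0 - sse) / 2) / s2
  p_rhythm <- if (sse <= .Machine$double.eps * sse0) 0 else pf(fstat, 2, df2, lower.tail = FALSE)

  beta <- unname(co[["cosw"]])
  gamma <- unname(co[["sinw"]])
  amp <- sqrt(beta^2 + gamma^2)
  peak <- .peak_hour(beta, gamma, period)

  # delta-method SEs for amplitude and peak hour from the OLS covariance
  xtx_inv <- chol2inv(chol(crossprod(X)))
  vc <- s2 * xtx_inv
  se_mesor <- sqrt(vc[1, 1])
  if (amp > 1e-12) {
    g_amp <- c(0, beta / amp, gamma / amp)
    g_peak <- c(0, -gamma / (w * amp^2), beta / (w * amp^2))
    se_amp <- sqrt(drop(t(g_amp) %*% vc %*% g_amp))
    se_peak <- sqrt(drop(t(g_peak) %*% vc %*% g_peak))
  } else {
    se_amp <- NA_real_
    se_peak <- NA_real_
  }

  out <- list(
    mesor = unname(co[["intercept"]]), amplitude = amp, peak_hour = peak,
    beta = beta, gamma = gamma,
    residual_sd = sqrt(s2), p_rhythm = p_rhythm, n_obs = n, period = period,
    se = c(mesor = se_mesor, amplitude = se_amp, peak_hour = se_peak),
    data = tibble::tibble(time = times, value = values,
                          fitted = values - res)
  )
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period ", x$period, " h, n = ", x$n_obs, ")\n", sep = "")
  cat(sprintf("  MESOR     %.4g\n  amplitude %.4g\n  peak hour %.4g\n",
              x$mesor, x$amplitude, x$peak_hour))
  cat(sprintf("  rhythmicity p = %.3g (zero-amplitude F-test)\n", x$p_rhythm))
  invisible(x)
}

#' Aggregate a raw stream into fixed-width time bins
#'
#' Collapses an irregular time series (e.g. per-second actigraphy counts or
#' beat-to-beat heart-rate samples) into regular bins of `bin_minutes`
#' minutes, applying `reducer` to the values falling in each bin. Activity
#' counts are conventionally summed; rate-like variables averaged.
#'
#' @param times Numeric hours since an arbitrary origin, or a `POSIXct`
#'   vector (converted to hours since midnight of the first day).
#' @param values Numeric vector, same length as `times`.
#' @param bin_minutes Bin width in minutes; must be positive.
#' @param reducer Function applied to the values in each bin (default `sum`).
#' @return A tibble with one row per non-empty bin: `time_h` (bin midpoint in
#'   hours) and `value`. Empty input yields an empty tibble.
#' @export
aggregate_bins <- function(times, values, bin_minutes = 1, reducer = sum) {
  stopifnot(bin_minutes > 0)
  if (inherits(times, "POSIXct")) {
    origin <- as.POSIXct(format(min(times), "%Y-%m-%d"), tz = attr(times, "tzone") %||% "")
    times <- as.numeric(difftime(times, origin, units = "hours"))
  }
  stopifnot(is.numeric(times), length(times) == length(values))
  if (length(times) == 0) {
    return(tibble::tibble(time_h = numeric(), value = numeric()))
  }
  bin <- floor(times * 60 / bin_minutes)
  tibble::tibble(bin = bin, value = values) |>
    dplyr::summarise(value = reducer(.data$value), .by = "bin") |>
    dplyr::arrange(.data$bin) |>
    dplyr::transmute(time_h = (.data$bin + 0.5) * bin_minutes / 60,
                     value = .data$value)
}

#' Two-sided Wilcoxon rank-sum test with an explicit exact branch
#'
#' Compares two independent samples by the rank-sum (Mann-Whitney) test.
#' The exact null distribution is used when the smaller sample has at most
#' `exact_max` observations and the pooled data contain no ties; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used. The branch taken is recorded in the result.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest size of the smaller sample for which the exact
#'   distribution is used (default 10).
#' @return A one-row tibble: `statistic` (Mann-Whitney W for `x`), `p_value`
#'   (two-sided) and `exact` (logical branch flag).
#' @examples
#' ranksum_exact(c(1, 2), c(3, 4))  # p = 1/3
#' @export
ranksum_exact <- function(x, y, exact_max = 10) {
  stopifnot(length(x) > 0, length(y) > 0)
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    exact = use_exact
  )
}
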
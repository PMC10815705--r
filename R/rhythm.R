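# cosinor rhythmometry of bioluminescence reporter traces, moving-average
# detrending, and dual-luciferase endpoint normalisation

as_timeseries <- function(ts) {
  if (is.data.frame(ts) && ncol(ts) >= 2L) {
    out <- data.frame(time = as.numeric(ts[[1L]]),
                      signal = as.numeric(ts[[2L]]))
  } else {
    stop("time series must be a data frame with time and signal columns",
         call. = FALSE)
  }
  if (anyNA(out$time) || anyNA(out$signal)) {
    stop("time series contains missing values", call. = FALSE)
  }
  if (any(diff(out$time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  out
}

#' Moving-average detrending of a time series
#'
#' Subtracts a centred moving average of width `window` hours (for plotting
#' parity with detrended reporter traces; for fitting, prefer the linear
#' trend term inside [cosinor_fit()], which needs no edge trimming). A
#' window of one full period annihilates the oscillatory component of its
#' average, leaving the rhythm intact. The half-window at each edge, where
#' the average is undefined, is trimmed from the output.
#'
#' @param ts Data frame, first column time in hours (regular grid),
#'   second column signal.
#' @param window Moving-average width in hours; must be positive and
#'   smaller than the record duration.
#' @return Data frame `time_h`, `signal` restricted to the interior.
#' @export
detrend <- function(ts, window = 24) {
  ts <- as_timeseries(ts)
  duration <- max(ts$time) - min(ts$time)
  if (window <= 0 || window >= duration) {
    stop("window must lie in (0, duration)", call. = FALSE)
  }
  dt <- median(diff(ts$time))
  half <- floor(window / (2 * dt))
  if (half < 1L) stop("window shorter than the sampling interval",
                      call. = FALSE)
  w <- 2L * half + 1L
  # trapezoidal weights: the two endpoints of the window sit one full
  # window apart, so they get half weight; a window of exactly one period
  # then averages a pure cosine to zero on a commensurate grid
  wts <- c(0.5, rep(1, w - 2L), 0.5) / (w - 1L)
  ma <- stats::filter(ts$signal, wts, sides = 2)
  keep <- !is.na(ma)
  data.frame(time_h = ts$time[keep],
             signal = ts$signal[keep] - as.numeric(ma[keep]))
}

#' Cosinor fit of a rhythmic time series
#'
#' Ordinary least squares of
#' `y = M + b t + beta_c cos(2 pi t / tau) + beta_s sin(2 pi t / tau)`:
#' mesor `M` (rhythm-adjusted mean), amplitude `A = sqrt(beta_c^2 +
#' beta_s^2)` (half peak-to-trough), acrophase `phi = (tau / 2 pi)
#' atan2(beta_s, beta_c)` mapped into `[0, tau)` (peak time), and optional
#' linear trend `b`. Damping is deliberately not modelled — the classical
#' cosinor is undamped — so on strongly damped signals the amplitude
#' estimate is an average over the record.
#'
#' Rhythmicity is the F-test of `(beta_c, beta_s)` jointly zero against the
#' trend-only (or mean-only) reduced model. Relative amplitude, `100 A / M`
#' (% of mesor), is reported only when the fit is `applicable`:
#' rhythmicity p < 0.05 and `M > 0`; otherwise it is `NA` (not applicable),
#' the convention used for arrhythmic traces.
#'
#' With `free_period = TRUE` the period is chosen from `period_grid` by
#' minimum residual sum of squares; the grid is restricted to periods with
#' at least two full cycles of coverage (a coverage of >= 2 periods is
#' required for any fit).
#'
#' @param ts Data frame, first column time in hours, second column signal.
#' @param period Fixed period in hours (default 24).
#' @param fit_trend Include the linear trend term (default `TRUE`).
#' @param free_period Grid-search the period instead of fixing it.
#' @param period_grid Candidate periods in hours for the grid search;
#'   bounded to roughly circadian values by default to avoid aliasing.
#' @return Object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase`, `period`, `trend_slope`, `relative_amplitude`,
#'   `rhythmicity_p`, `applicable`, `n`, `rss`.
#' @examples
#' t <- seq(0, 72, by = 1 / 3)
#' y <- 100 + 20 * cos(2 * pi * (t - 6) / 24)
#' fit <- cosinor_fit(data.frame(t, y))
#' c(fit$mesor, fit$amplitude, fit$acrophase) # 100 20 6
#' @export
cosinor_fit <- function(ts, period = 24, fit_trend = TRUE,
                        free_period = FALSE,
                        period_grid = seq(20, 28, by = 0.1)) {
  ts <- as_timeseries(ts)
  t <- ts$time
  y <- ts$signal
  n <- length(y)
  if (n < 4L) stop("too few points for a cosinor fit (need >= 4)",
                   call. = FALSE)
  duration <- max(t) - min(t)

  fit_one <- function(tau) {
    X <- if (fit_trend) {
      cbind(1, t, cos(2 * pi * t / tau), sin(2 * pi * t / tau))
    } else {
      cbind(1, cos(2 * pi * t / tau), sin(2 * pi * t / tau))
    }
    f <- stats::lm.fit(X, y)
    list(tau = tau, coef = f$coefficients, rss = sum(f$residuals^2),
         rank = f$rank, p_params = ncol(X))
  }

  if (free_period) {
    grid <- period_grid[duration >= 2 * period_grid]
    if (length(grid) == 0L) {
      stop("no grid period with >= 2 full cycles of coverage", call. = FALSE)
    }
    fits <- lapply(grid, fit_one)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  } else {
    if (period <= 0) stop("period must be > 0", call. = FALSE)
    if (duration < 2 * period) {
      stop("need >= 2 full periods of coverage for fitting", call. = FALSE)
    }
    best <- fit_one(period)
  }
  if (best$rank < best$p_params || anyNA(best$coef)) {
    stop("singular cosinor design matrix", call. = FALSE)
  }

  tau <- best$tau
  cf <- best$coef
  mesor <- cf[[1L]]
  slope <- if (fit_trend) cf[[2L]] else 0
  bc <- cf[[length(cf) - 1L]]
  bs <- cf[[length(cf)]]
  amplitude <- sqrt(bc^2 + bs^2)
  acrophase <- ((tau / (2 * pi)) * atan2(bs, bc)) %% tau

  # F-test of the cosine pair against the reduced (mean +/- trend) model
  X0 <- if (fit_trend) cbind(1, t) else matrix(1, n, 1)
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  rss1 <- best$rss
  df2 <- n - best$p_params
  scale0 <- sum((y - mean(y))^2)
  tiny <- 1e-12 * (scale0 + .Machine$double.xmin)
  if (rss1 <= tiny) {
    p_rhythm <- if (rss0 - rss1 <= tiny) 1 else 0
  } else {
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p_rhythm <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  }

  applicable <- is.finite(p_rhythm) && p_rhythm < 0.05 && mesor > 0
  rel_amp <- if (applicable) 100 * amplitude / mesor else NA_real_

  structure(list(mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase, period = tau, trend_slope = slope,
                 relative_amplitude = rel_amp, rhythmicity_p = p_rhythm,
                 applicable = applicable, n = n, rss = rss1),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (n = %d, period = %.2f h)\n  mesor %.4g  amplitude %.4g  acrophase %.3f h  trend %.4g/h\n",
    x$n, x$period, x$mesor, x$amplitude, x$acrophase, x$trend_slope))
  cat(sprintf("  rhythmicity p = %.3g; relative amplitude = %s\n",
              x$rhythmicity_p,
              if (x$applicable) sprintf("%.2f%% of mesor",
                                        x$relative_amplitude) else "N/A"))
  invisible(x)
}

#' Cosinor fits for a table of traces, as a data frame
#'
#' @param traces Named list of time-series data frames.
#' @param ... Passed to [cosinor_fit()].
#' @return Data frame with one row per trace.
#' @export
cosinor_table <- function(traces, ...) {
  rows <- lapply(names(traces), function(nm) {
    f <- cosinor_fit(traces[[nm]], ...)
    data.frame(trace = nm, mesor = f$mesor, amplitude = f$amplitude,
               acrophase = f$acrophase, period = f$period,
               trend_slope = f$trend_slope,
               relative_amplitude = f$relative_amplitude,
               rhythmicity_p = f$rhythmicity_p, applicable = f$applicable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalise a dual-luciferase reporter assay
#'
#' Per well, the firefly/renilla ratio corrects for transfection
#' efficiency; ratios are then divided by the reference-group mean so the
#' reference (typically WT) mean is exactly 1. Wells with non-positive
#' renilla signal are excluded with a warning.
#'
#' @param assay Data frame with columns `well`, `group`, `firefly`,
#'   `renilla`.
#' @param reference_group Group whose mean ratio is scaled to 1
#'   (default `"WT"`).
#' @return The retained rows with added columns `ratio` and `normalized`.
#' @export
normalize_reporter <- function(assay, reference_group = "WT") {
  need <- c("well", "group", "firefly", "renilla")
  if (!all(need %in% names(assay))) {
    stop("assay must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(assay$renilla > 0) | is.na(assay$renilla)
  if (any(bad)) {
    warning("excluding well(s) with non-positive renilla signal: ",
            paste(assay$well[bad], collapse = ", "), call. = FALSE)
    assay <- assay[!bad, , drop = FALSE]
  }
  ref <- assay$group == reference_group
  if (!any(ref)) {
    stop("reference group '", reference_group, "' empty or absent",
         call. = FALSE)
  }
  assay$ratio <- assay$firefly / assay$renilla
  assay$normalized <- assay$ratio / mean(assay$ratio[ref])
  rownames(assay) <- NULL
  assay
}
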
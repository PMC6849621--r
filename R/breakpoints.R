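# Regime-shift detection by sequential t-tests (the STARS family) and an
# ARIMA forecasting interface.

#' Sequential t-test regime-shift detection
#'
#' Detects break points in a time series by the sequential t-test
#' algorithm: a candidate shift is declared when a value deviates from
#' the current regime mean by more than the critical difference implied
#' by a two-sided t-test at level `alpha` with `2 * cutoff - 2` degrees
#' of freedom; the candidate is confirmed only if the regime-shift index
#' (the cumulative normalised exceedance over the next `cutoff` points,
#' with outliers down-weighted by Huber's rule) stays positive throughout
#' the confirmation window.  Regime means are Huber-weighted: a point at
#' normalised distance `z` from the mean gets weight `min(1, huber/|z|)`.
#'
#' Serial correlation is handled by a first-order autoregressive
#' correction.  The lag-1 coefficient is estimated from the
#' autocorrelation of the first differences, which is insensitive to
#' mean shifts (for an AR(1) process the differenced series has lag-1
#' autocorrelation `(phi - 1) / 2`, and a shift contaminates only a
#' single trimmed difference).  By default the critical difference is
#' inflated by `sqrt((1 + phi) / (1 - phi))`, the variance inflation of
#' a mean of correlated points; this keeps full power against genuine
#' shifts, which a prewhitening filter would shrink by `1 - phi`.  The
#' filtering variant (`x[t] - phi * x[t-1]`) is also available.
#' Detected break indices refer to the original series; regime means are
#' recomputed from the original values.
#'
#' @param x Numeric series (finite values).
#' @param dates Optional vector of dates, one per value.
#' @param alpha Significance level of the sequential t-test
#'   (default 0.05).
#' @param cutoff Minimum regime length in points (default 5).
#' @param huber Huber weight parameter (default 1).
#' @param ar_correction `"adjust"` (default) inflates the critical
#'   difference for the estimated AR(1) coefficient; `"filter"`
#'   prewhitens the series; `"none"` disables the correction.
#' @return A list of class `"stars_result"`: `breaks` (indices of the
#'   first point of each new regime), `break_dates`, `rsi` (regime-shift
#'   index per break), `regime_means` (Huber-weighted mean of each
#'   regime, on the original scale), `regimes` (regime id per point),
#'   `ar1` (the prewhitening coefficient used) and the parameters.
#' @export
stars_detect <- function(x, dates = NULL, alpha = 0.05, cutoff = 5L,
                         huber = 1,
                         ar_correction = c("adjust", "filter", "none")) {
  ar_correction <- match.arg(ar_correction)
  x <- as.numeric(x)
  n <- length(x)
  cutoff <- as.integer(cutoff)
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite")
  if (n <= 2L * cutoff)
    stop("series length must exceed twice the cutoff")
  if (is.null(dates)) dates <- seq_len(n)
  if (length(dates) != n) stop("dates must match the series length")

  phi <- 0
  y <- x
  infl <- 1
  if (ar_correction != "none") phi <- ar1_from_differences(x)
  filtered <- ar_correction == "filter" && phi > 0
  if (filtered) y <- x[-1L] - phi * x[-n]
  if (ar_correction == "adjust" && phi > 0)
    infl <- ar1_mean_inflation(phi, cutoff)
  det <- stars_core(y, alpha, cutoff, huber, infl)
  breaks <- det$breaks
  if (filtered && length(breaks)) breaks <- breaks + 1L

  bounds <- c(1L, breaks, n + 1L)
  regimes <- rep(seq_len(length(bounds) - 1L),
                 times = diff(bounds))
  means <- vapply(split(x, regimes), function(seg)
    huber_mean(seg, sigma = det$sigma_l, huber = huber), numeric(1))
  out <- list(breaks = breaks,
              break_dates = dates[breaks],
              rsi = det$rsi,
              regime_means = unname(means),
              regimes = regimes,
              ar1 = phi,
              sigma_l = det$sigma_l,
              params = list(alpha = alpha, cutoff = cutoff, huber = huber,
                            ar_correction = ar_correction))
  class(out) <- "stars_result"
  out
}

#' @export
print.stars_result <- function(x, ...) {
  if (length(x$breaks) == 0L) {
    cat("No regime shifts detected.\n")
  } else {
    cat("Regime shifts at: ",
        paste(format(x$break_dates, trim = TRUE), collapse = ", "),
        "\n", sep = "")
    cat("Regime means: ",
        paste(format(x$regime_means, digits = 4), collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

# Core sequential detection on a (possibly prewhitened) series.
stars_core <- function(y, alpha, cutoff, huber, infl = 1) {
  n <- length(y)
  l <- cutoff
  # typical within-window variance over consecutive l-point windows;
  # the median (rescaled to be consistent for Gaussian noise) is immune
  # to the few shift-straddling windows that would inflate the mean
  nw <- n - l + 1L
  vars <- vapply(seq_len(nw), function(i) stats::var(y[i:(i + l - 1L)]),
                 numeric(1))
  sigma_l <- sqrt(median(vars) / (qchisq(0.5, l - 1L) / (l - 1L)))
  if (!is.finite(sigma_l) || sigma_l == 0) sigma_l <- .Machine$double.eps
  crit <- qt(1 - alpha / 2, df = 2L * l - 2L) * sigma_l * sqrt(2 / l) * infl

  breaks <- integer(0)
  rsi_out <- numeric(0)
  start <- 1L
  mean_cur <- huber_mean(y[start:(start + l - 1L)], sigma_l, huber)
  t <- start + l
  while (t <= n) {
    dev <- y[t] - mean_cur
    # a shift needs a full confirmation window: candidates too close to
    # the series end cannot be sustained over `cutoff` points
    if (abs(dev) > crit && t + l - 1L <= n) {
      sgn <- sign(dev)
      level <- mean_cur + sgn * crit
      last <- t + l - 1L
      seg <- y[t:last]
      w <- huber_weights((seg - level) * sgn / sigma_l, huber)
      rsi_series <- cumsum(w * (seg - level) * sgn) / (l * sigma_l)
      if (all(rsi_series > 0)) {
        breaks <- c(breaks, t)
        rsi_out <- c(rsi_out, rsi_series[length(rsi_series)])
        start <- t
        mean_cur <- huber_mean(y[start:last], sigma_l, huber)
        t <- t + 1L
        next
      }
    }
    # no shift: absorb the point into the current regime
    mean_cur <- huber_mean(y[start:t], sigma_l, huber)
    t <- t + 1L
  }
  list(breaks = breaks, rsi = rsi_out, sigma_l = sigma_l)
}

huber_weights <- function(z, huber) {
  az <- abs(z)
  ifelse(az <= huber | az == 0, 1, huber / az)
}

# Huber-weighted mean, iterated to stability.
huber_mean <- function(seg, sigma, huber) {
  mu <- median(seg)
  if (!is.finite(sigma) || sigma == 0) return(mean(seg))
  for (i in 1:20) {
    w <- huber_weights((seg - mu) / sigma, huber)
    mu_new <- sum(w * seg) / sum(w)
    if (abs(mu_new - mu) < 1e-12) break
    mu <- mu_new
  }
  mu
}

# Exact inflation of the standard error of an l-point mean under lag-1
# autocorrelation phi, relative to white noise.
ar1_mean_inflation <- function(phi, l) {
  k <- seq_len(l - 1L)
  sqrt(1 + 2 * sum((1 - k / l) * phi^k))
}

# AR(1) coefficient from the lag-1 autocorrelation of first differences:
# for x AR(1) with coefficient phi, the differenced series has lag-1
# autocorrelation (phi - 1)/2, and differencing removes regime-mean
# contamination except at the break itself, which appears as a single
# outlying difference pair.  The autocorrelation is estimated as a
# Huber-robust regression slope of d[t+1] on d[t], so that pair carries
# almost no weight while pure-noise estimates stay unbiased.
ar1_from_differences <- function(x) {
  d <- diff(x)
  nd <- length(d)
  if (nd < 6L || sd(d) == 0) return(0)
  d <- d - median(d)
  x1 <- d[-nd]; x2 <- d[-1L]
  s <- sd(d)
  b <- sum(x1 * x2) / sum(x1^2)
  for (i in 1:10) {
    res <- x2 - b * x1
    w <- huber_weights(res / s, 1.5) * huber_weights(x1 / s, 2.5)
    b_new <- sum(w * x1 * x2) / sum(w * x1^2)
    if (!is.finite(b_new) || abs(b_new - b) < 1e-8) break
    b <- b_new
  }
  if (!is.finite(b)) return(0)
  min(max(1 + 2 * b, 0), 0.95)
}

#' Fit an ARIMA model before a split date and forecast beyond it
#'
#' Selects the differencing order by a Phillips-Perron unit-root test on
#' the pre-split segment (`d = 1` when the test fails to reject
#' non-stationarity at the 5% level, else `d = 0`), then picks the
#' AR and MA orders by AIC over a small grid, fits on the pre-split
#' segment only, and forecasts `horizon` steps with 95% prediction
#' intervals.  If post-split observations are available they are
#' compared with the intervals; a transition is flagged when values fall
#' outside.
#'
#' @param x Numeric series.
#' @param dates Dates, one per value (default indices).
#' @param split Last date included in the fit.
#' @param horizon Steps to forecast (default: number of post-split
#'   points, or 10 if none).
#' @param max_p,max_q Grid maxima for the AR and MA orders (default 2).
#' @return A list of class `"forecast_result"`: `order` (p, d, q),
#'   `forecast` (data frame: step, point, lower, upper, observed where
#'   available, outside), `transition_consistent` (any post-split value
#'   outside its interval), `aic`, and the fitted model.
#' @export
fit_forecast <- function(x, dates = NULL, split, horizon = NULL,
                         max_p = 2L, max_q = 2L) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(dates)) dates <- seq_len(n)
  pre <- x[dates <= split]
  post <- x[dates > split]
  if (length(pre) < 10L) stop("pre-split segment must hold at least 10 points")
  if (is.null(horizon)) horizon <- if (length(post)) length(post) else 10L

  d <- tryCatch(
    if (PP.test(pre)$p.value > 0.05) 1L else 0L,
    error = function(e) 0L)
  best <- NULL; best_aic <- Inf; best_order <- c(0L, d, 0L)
  for (p in 0:max_p) for (q in 0:max_q) {
    fit <- tryCatch(
      arima(pre, order = c(p, d, q), method = "ML"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    a <- AIC(fit)
    if (is.finite(a) && a < best_aic) {
      best <- fit; best_aic <- a; best_order <- c(p, d, q)
    }
  }
  if (is.null(best))
    stop("non-stationary fit failure: no ARIMA model on the grid converged")
  pr <- predict(best, n.ahead = horizon)
  z <- qnorm(0.975)
  fc <- data.frame(step = seq_len(horizon),
                   point = as.numeric(pr$pred),
                   lower = as.numeric(pr$pred - z * pr$se),
                   upper = as.numeric(pr$pred + z * pr$se))
  fc$observed <- c(post[seq_len(min(length(post), horizon))],
                   rep(NA_real_, max(0L, horizon - length(post))))
  fc$outside <- !is.na(fc$observed) &
    (fc$observed < fc$lower | fc$observed > fc$upper)
  out <- list(order = setNames(best_order, c("p", "d", "q")),
              forecast = fc,
              transition_consistent = any(fc$outside),
              aic = best_aic,
              model = best)
  class(out) <- "forecast_result"
  out
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("arima(%d, %d, %d), AIC %.2f; %d-step forecast%s\n",
              x$order[1L], x$order[2L], x$order[3L], x$aic,
              nrow(x$forecast),
              if (x$transition_consistent)
                "; post-split values leave the 95% prediction interval"
              else ""))
  invisible(x)
}
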
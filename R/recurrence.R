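#' Extract recurrence intervals above a threshold
#'
#' Event hours are the positions where the (diurnally adjusted) series
#' strictly exceeds `q`; recurrence intervals are the integer-hour gaps
#' between consecutive events.  Consecutive exceedances yield intervals of
#' one hour, so clustered extremes show up as runs of 1s.  Missing hours can
#' never be events.
#'
#' @param x An `adjusted_series`/`hourly_series`, or a plain numeric vector.
#' @param q Positive threshold on the adjusted scale.
#' @return A `recurrence_series`: list with `q`, `event_times` (hour indices),
#'   `durations` (hours, length one less than the number of events),
#'   `mean_duration`, `n_hours`, and `too_few` flag (fewer than 2 events).
#' @export
extract_recurrence <- function(x, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0) {
    stop_riacd("'q' must be a positive scalar", "riacd_validation_error")
  }
  v <- if (inherits(x, "hourly_series")) x$values else as.numeric(x)
  ev <- which(!is.na(v) & v > q)
  dur <- diff(ev)
  structure(
    list(q = q, event_times = ev, durations = as.numeric(dur),
         mean_duration = if (length(dur)) mean(dur) else NA_real_,
         n_hours = length(v), too_few = length(ev) < 2L),
    class = "recurrence_series"
  )
}

#' @export
print.recurrence_series <- function(x, ...) {
  cat(sprintf("<recurrence_series> q = %.2f: %d events over %d hours, <d> = %.2f h\n",
              x$q, length(x$event_times), x$n_hours, x$mean_duration))
  invisible(x)
}

#' Exceedance probability versus reciprocal mean interval
#'
#' For an i.i.d. series the exceedance probability P(x > q) equals the
#' reciprocal of the mean recurrence interval; this diagnostic returns both
#' empirical sides so the caller can compare them.
#'
#' @inheritParams extract_recurrence
#' @return List with `q`, `p_exceed` (fraction of present hours above `q`) and
#'   `recip_mean_interval` (1 / mean duration).
#' @export
exceedance_check <- function(x, q) {
  rec <- extract_recurrence(x, q)
  if (rec$too_few) {
    stop_riacd("need at least two exceedances", "riacd_insufficient_data_error")
  }
  v <- if (inherits(x, "hourly_series")) x$values else as.numeric(x)
  v <- v[!is.na(v)]
  list(q = q, p_exceed = mean(v > q),
       recip_mean_interval = 1 / rec$mean_duration)
}

#' Spatially reviewed recurrence intervals
#'
#' Each time an interval at the base station i completes (at event hour t_s),
#' look up the most recently completed interval at neighbour j under the same
#' threshold -- including one completing exactly at t_s.  Before j's first
#' interval has completed, j's whole-series mean interval is used as an
#' ad hoc fill.  The reviewed sequence has exactly the length of the base
#' durations, which is what lets the two be used as an aligned pair.
#'
#' @param base `recurrence_series` at station i (needs >= 2 events).
#' @param neighbour `recurrence_series` at station j, same threshold, same
#'   hour axis.
#' @return A `spatial_review_pair`: list with `base`, `reviewed` (same length
#'   as `base$durations`), `fill_value`, `n_filled`, `all_fill` flag.
#' @export
spatially_reviewed <- function(base, neighbour) {
  stopifnot(inherits(base, "recurrence_series"),
            inherits(neighbour, "recurrence_series"))
  if (!isTRUE(all.equal(base$q, neighbour$q))) {
    stop_riacd("thresholds of the two series differ", "riacd_config_error")
  }
  if (base$too_few) {
    stop_riacd("base series has no completed intervals",
               "riacd_insufficient_data_error")
  }
  t_s <- base$event_times[-1L]
  compl <- neighbour$event_times[-1L]
  e <- neighbour$durations
  all_fill <- length(e) == 0L
  fill <- if (all_fill) mean(base$durations) else mean(e)
  if (all_fill) {
    reviewed <- rep(fill, length(t_s))
    n_filled <- length(t_s)
  } else {
    idx <- findInterval(t_s, compl)
    reviewed <- ifelse(idx > 0L, e[pmax(idx, 1L)], fill)
    n_filled <- sum(idx == 0L)
  }
  structure(
    list(base = base, reviewed = as.numeric(reviewed), fill_value = fill,
         n_filled = n_filled, all_fill = all_fill),
    class = "spatial_review_pair"
  )
}

#' @export
print.spatial_review_pair <- function(x, ...) {
  cat(sprintf("<spatial_review_pair> q = %.2f: %d aligned intervals (%d filled%s)\n",
              x$base$q, length(x$reviewed), x$n_filled,
              if (x$all_fill) ", neighbour empty" else ""))
  invisible(x)
}

#' Maximal significant autoregressive lag
#'
#' Fits a single AR(`max_lag`) model to a duration series by OLS and returns
#' the largest lag whose coefficient is significant in a two-sided Wald test
#' at level `conf`; 0 when none is.
#'
#' @param d A `recurrence_series` or numeric duration vector.
#' @param max_lag Order of the AR fit (default 10).
#' @param conf Confidence level (default 0.95).
#' @return Integer L in `0:max_lag`.
#' @export
ar_max_significant_lag <- function(d, max_lag = 10L, conf = 0.95) {
  v <- if (inherits(d, "recurrence_series")) d$durations else as.numeric(d)
  if (length(v) <= max_lag + 10L) {
    stop_riacd("series too short for the requested AR order",
               "riacd_insufficient_data_error")
  }
  f <- ar.ols(v, aic = FALSE, order.max = max_lag, demean = TRUE,
              intercept = TRUE)
  z <- drop(f$ar) / drop(f$asy.se.coef$ar)
  crit <- qnorm(1 - (1 - conf) / 2)
  sig <- which(abs(z) > crit)
  if (length(sig)) max(sig) else 0L
}

# First-order detrended fluctuation analysis.  Returns log2 window sizes and
# log2 fluctuation amplitudes.
dfa1_fluctuations <- function(x, sizes) {
  y <- cumsum(x - mean(x))
  n_tot <- length(y)
  vapply(sizes, function(n) {
    k <- n_tot %/% n
    m <- matrix(y[seq_len(k * n)], nrow = n)
    t1 <- seq_len(n)
    X <- cbind(1, t1)
    # residual-maker applied to all segments at once
    resid <- m - X %*% solve(crossprod(X), crossprod(X, m))
    sqrt(mean(resid^2))
  }, numeric(1))
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' DFA of order 1 over logarithmically spaced window sizes from 8 to
#' length/4; H is the slope of log fluctuation versus log window size, with
#' its regression standard error.  H near 0.5 indicates an uncorrelated
#' series, H > 0.5 persistence.
#'
#' @param x Numeric series of length >= 100 (NAs dropped).
#' @param n_windows Number of window sizes in the log-spaced grid.
#' @return List with `H`, `se`, and the `sizes`/`fluctuations` used.
#' @export
hurst_exponent <- function(x, n_windows = 12L) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) < 100L) {
    stop_riacd("need at least 100 observations for DFA",
               "riacd_insufficient_data_error")
  }
  sizes <- unique(round(exp(seq(log(8), log(length(x) / 4),
                                length.out = n_windows))))
  fl <- dfa1_fluctuations(x, sizes)
  fit <- lm(log(fl) ~ log(sizes))
  s <- summary(fit)$coefficients
  list(H = unname(s[2L, 1L]), se = unname(s[2L, 2L]),
       sizes = sizes, fluctuations = fl)
}

#' Temporal-structure scan of recurrence series
#'
#' Convenience wrapper computing, per adjusted series and threshold, the
#' maximal significant AR lag and the DFA Hurst exponent of the duration
#' sequence.
#'
#' @param x An `adjusted_series`.
#' @param thresholds Numeric vector of thresholds.
#' @param max_lag AR scan order.
#' @return Data frame with columns `q`, `n_events`, `L`, `H`, `H_se` (NA where
#'   a series is too short for an estimator).
#' @export
scaling_report <- function(x, thresholds = seq(2, 4, by = 0.5), max_lag = 10L) {
  rows <- lapply(thresholds, function(q) {
    rec <- extract_recurrence(x, q)
    L <- tryCatch(ar_max_significant_lag(rec, max_lag = max_lag),
                  riacd_insufficient_data_error = function(e) NA_integer_)
    hu <- tryCatch(hurst_exponent(rec$durations),
                   riacd_insufficient_data_error = function(e) NULL)
    data.frame(q = q, n_events = length(rec$event_times), L = L,
               H = hu$H %||% NA_real_, H_se = hu$se %||% NA_real_)
  })
  do.call(rbind, rows)
}
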
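# Iterate the fitted recursion h steps beyond the end of (d, psi, review
# histories).  Unrealized future durations are replaced by their conditional
# expectation psi-hat (valid because E[d | I] = psi); reviewed durations are
# held at their last observed value.
forecast_recursion <- function(params, d_hist, psi_hist, review_hist, h) {
  order <- implied_order(params)
  m <- mean(d_hist)
  n <- length(d_hist)
  d_ext <- c(rep(m, order$L_d), d_hist)
  psi_ext <- c(rep(m, order$L_psi), psi_hist)
  out <- numeric(h)
  for (step in seq_len(h)) {
    psi_next <- params$omega
    for (u in seq_len(order$L_d)) {
      psi_next <- psi_next + params$alpha[u] * d_ext[length(d_ext) + 1L - u]
    }
    for (v in seq_len(order$L_psi)) {
      psi_next <- psi_next + params$beta[v] * psi_ext[length(psi_ext) + 1L - v]
    }
    if (order$L_j > 0L) {
      for (j in seq_len(nrow(params$gamma))) {
        last_rv <- review_hist[nrow(review_hist), j]
        for (k in seq_len(order$L_j)) {
          idx <- nrow(review_hist) + step - k
          val <- if (idx <= nrow(review_hist)) review_hist[idx, j] else last_rv
          psi_next <- psi_next + params$gamma[j, k] * params$weights[j] * val
        }
      }
    }
    out[step] <- psi_next
    d_ext <- c(d_ext, psi_next)      # substitute psi-hat for unrealized d
    psi_ext <- c(psi_ext, psi_next)
  }
  out
}

fit_state <- function(fit) {
  list(params = fit$params,
       d = fit$d, psi = fit$path$psi,
       review = fit$d_review)
}

resolve_forecast_input <- function(fit, state) {
  if (!is.null(state)) {
    rv <- state$review
    if (!is.null(rv) && !is.matrix(rv)) rv <- matrix(rv, ncol = 1L)
    return(list(params = state$params, d = state$d, psi = state$psi,
                review = rv))
  }
  if (!inherits(fit, "acd_fit")) {
    stop_riacd("supply a fitted model or an explicit state", "riacd_state_error")
  }
  fit_state(fit)
}

#' One-step-ahead forecast of the next recurrence interval
#'
#' `psi_hat_{s+1} = omega + sum_u alpha_u d_{s+1-u} + sum_v beta_v psi_{s+1-v}
#'  + spatial terms`, evaluated at the fitted coefficients from the end of
#' the sample (or from an explicit `state`).
#'
#' @param fit An [fit_acd()] result.
#' @param state Optional list with `params` ([sacd_params]), `d` (duration
#'   history), `psi` (conditional-duration history) and `review` (matrix of
#'   reviewed durations), overriding the fit's own state.
#' @return Forecast `psi_hat` (> 0), in hours.
#' @export
one_step_forecast <- function(fit, state = NULL) {
  st <- resolve_forecast_input(fit, state)
  check_state(st)
  forecast_recursion(st$params, st$d, st$psi, st$review, 1L)
}

check_state <- function(st) {
  order <- implied_order(st$params)
  if (length(st$d) < order$L_d || length(st$psi) < order$L_psi ||
      (order$L_j > 0L &&
       (is.null(st$review) || nrow(st$review) < order$L_j))) {
    stop_riacd("incomplete state for the model order", "riacd_state_error")
  }
}

#' Multi-step forecasts of upcoming recurrence intervals
#'
#' Iterates the fitted recursion `h` steps, substituting each forecast for
#' the corresponding unrealized duration; reviewed durations are held at
#' their last observed value.  For a stationary uncoupled fit the sequence
#' converges geometrically to `omega / (1 - alpha - beta)`.
#'
#' @inheritParams one_step_forecast
#' @param h Forecast horizon (>= 1).
#' @return Numeric vector `psi_hat[1..h]`.
#' @export
multi_step_forecast <- function(fit, h, state = NULL) {
  if (!is_count(h, min = 1L)) {
    stop_riacd("'h' must be a positive integer", "riacd_domain_error")
  }
  st <- resolve_forecast_input(fit, state)
  check_state(st)
  forecast_recursion(st$params, st$d, st$psi, st$review, as.integer(h))
}

#' Rolling out-of-sample forecast test
#'
#' For each of the last `holdout` durations, forecast one step ahead from all
#' data strictly before it and compare with the realized value.  In
#' `"refit"` mode (default) the model is re-estimated at every origin on the
#' expanding window; `"fixed"` mode fits once on the pre-holdout sample and
#' only rolls the recursion states forward.  Non-convergent refits are
#' flagged and excluded from the error averages, never imputed.
#'
#' @param d Full duration series.
#' @param d_review Reviewed durations aligned with `d` (or `NULL`).
#' @param order A [sacd_order].
#' @param family Innovation family.
#' @param holdout Number of held-out final durations (default 30).
#' @param mode `"refit"` or `"fixed"`.
#' @param ... Passed to [fit_acd()] (e.g. `restarts`).
#' @return List with `records` (data frame: origin, horizon, psi_hat,
#'   realized, ae, converged), `summary` (see [summarize_errors()]), and
#'   `n_failed`.
#' @export
rolling_forecast <- function(d, d_review = NULL, order = sacd_order(1L, 1L),
                             family = c("exponential", "weibull"),
                             holdout = 30L, mode = c("refit", "fixed"), ...) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  d <- as.numeric(d)
  N <- length(d)
  if (N <= holdout + 30L) {
    stop_riacd("series too short for the requested holdout",
               "riacd_insufficient_data_error")
  }
  J <- length(order$neighbours)
  rv <- if (order$L_j > 0L) as_review_matrix(d_review, N, J) else NULL
  origins <- seq.int(N - holdout + 1L, N)

  base_fit <- NULL
  if (mode == "fixed") {
    base_fit <- fit_acd(d[seq_len(origins[1L] - 1L)],
                        d_review = if (!is.null(rv))
                          rv[seq_len(origins[1L] - 1L), , drop = FALSE],
                        order = order, family = family, ...)
  }
  rows <- lapply(origins, function(s0) {
    ins <- seq_len(s0 - 1L)
    rec <- tryCatch({
      if (mode == "refit") {
        f <- fit_acd(d[ins],
                     d_review = if (!is.null(rv)) rv[ins, , drop = FALSE],
                     order = order, family = family, ...)
        one_step_forecast(f)
      } else {
        path <- conditional_path(base_fit$params, d[ins],
                                 if (!is.null(rv)) rv[ins, , drop = FALSE])
        one_step_forecast(NULL, state = list(
          params = base_fit$params, d = d[ins], psi = path$psi,
          review = if (!is.null(rv)) rv[ins, , drop = FALSE]))
      }
    }, error = function(e) NA_real_)
    data.frame(origin = s0, horizon = 1L, psi_hat = rec, realized = d[s0],
               ae = abs(rec - d[s0]), converged = is.finite(rec))
  })
  records <- do.call(rbind, rows)
  list(records = records, summary = summarize_errors(records),
       n_failed = sum(!records$converged))
}

#' Summarize out-of-sample forecast errors
#'
#' Breakpoint fractions `p(AE < b)` at the standard breakpoints (1, 6, 12,
#' 24, 48, 96 hours), the average absolute error, and the RMSE over the
#' holdout (`sqrt(mean((d - psi_hat)^2))`).  Fractions are non-decreasing in
#' the breakpoint by construction.
#'
#' @param records Data frame of forecast records (from [rolling_forecast()],
#'   needs columns `psi_hat`, `realized`, `ae`; rows with `converged = FALSE`
#'   are dropped).
#' @param breakpoints AE breakpoints in hours.
#' @return One-row data frame: `p_ae_lt_<b>` per breakpoint, `avg_ae`,
#'   `rmse`, `n_records`.
#' @export
summarize_errors <- function(records, breakpoints = c(1, 6, 12, 24, 48, 96)) {
  if (!nrow(records)) {
    stop_riacd("no forecast records to summarize", "riacd_validation_error")
  }
  if ("converged" %in% names(records)) {
    records <- records[records$converged, , drop = FALSE]
  }
  ae <- records$ae
  fr <- vapply(breakpoints, function(b) mean(ae < b), numeric(1))
  out <- as.data.frame(as.list(fr))
  names(out) <- sprintf("p_ae_lt_%g", breakpoints)
  out$avg_ae <- mean(ae)
  out$rmse <- sqrt(mean((records$realized - records$psi_hat)^2))
  out$n_records <- nrow(records)
  out
}
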
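# ---- internal parameter-vector plumbing --------------------------------------

theta_names <- function(order, family) {
  J <- length(order$neighbours)
  nm <- c("omega",
          if (order$L_d > 0L) paste0("alpha", seq_len(order$L_d)),
          if (order$L_psi > 0L) paste0("beta", seq_len(order$L_psi)),
          if (order$L_j > 0L)
            as.vector(outer(seq_len(J), seq_len(order$L_j),
                            function(j, k) sprintf("gamma%d.%d", j, k))),
          if (family == "weibull") "k")
  nm
}

theta_split <- function(theta, order, family) {
  J <- length(order$neighbours)
  i <- 1L
  omega <- theta[i]; i <- i + 1L
  alpha <- if (order$L_d > 0L) theta[i + seq_len(order$L_d) - 1L] else numeric()
  i <- i + order$L_d
  beta <- if (order$L_psi > 0L) theta[i + seq_len(order$L_psi) - 1L] else numeric()
  i <- i + order$L_psi
  gamma <- NULL
  if (order$L_j > 0L) {
    gamma <- matrix(theta[i + seq_len(J * order$L_j) - 1L], nrow = J)
    i <- i + J * order$L_j
  }
  k <- if (family == "weibull") theta[i] else 1
  list(omega = omega, alpha = alpha, beta = beta, gamma = gamma, k = k)
}

# Recursion without validation, tolerant of slightly negative coefficients
# (needed for numerical differentiation at boundary estimates).
cond_path_raw <- function(p, order, d, rv, weights) {
  n <- length(d)
  m <- mean(d)
  z <- rep(p$omega, n)
  for (u in seq_len(order$L_d)) {
    z <- z + p$alpha[u] * c(rep(m, u), d)[seq_len(n)]
  }
  if (order$L_j > 0L) {
    for (j in seq_len(nrow(p$gamma))) {
      for (k in seq_len(order$L_j)) {
        z <- z + p$gamma[j, k] * weights[j] * c(rep(m, k), rv[, j])[seq_len(n)]
      }
    }
  }
  if (order$L_psi > 0L) {
    as.numeric(filter(z, p$beta, method = "recursive",
                      init = rep(m, order$L_psi)))
  } else {
    z
  }
}

# Per-observation negative log-likelihood contributions for s = 2..N (the
# first duration conditions but does not contribute).  NULL signals an
# inadmissible evaluation point.
nll_contribs <- function(theta, order, family, d, rv, weights) {
  p <- theta_split(theta, order, family)
  if (!all(is.finite(theta)) || p$omega <= 0) return(NULL)
  psi <- cond_path_raw(p, order, d, rv, weights)
  if (any(!is.finite(psi)) || any(psi <= 0)) return(NULL)
  psi <- psi[-1L]; ds <- d[-1L]
  if (family == "exponential") {
    log(psi) + ds / psi
  } else {
    if (p$k <= 0) return(NULL)
    lam <- 1 / gamma(1 + 1 / p$k)  # overflows to 0 for k below ~0.006
    if (!is.finite(lam) || lam <= 0) return(NULL)
    -(dweibull(ds / psi, shape = p$k, scale = lam, log = TRUE) - log(psi))
  }
}

nll_total <- function(theta, order, family, d, rv, weights) {
  ct <- nll_contribs(theta, order, family, d, rv, weights)
  if (is.null(ct) || any(!is.finite(ct))) return(1e10)
  sum(ct)
}

num_gradient_matrix <- function(fn, theta) {
  # central differences of a vector-valued fn over theta; rows = observations
  p <- length(theta)
  base <- fn(theta)
  out <- matrix(NA_real_, length(base), p)
  for (r in seq_len(p)) {
    h <- max(1e-5 * abs(theta[r]), 1e-6)
    up <- theta; up[r] <- up[r] + h
    dn <- theta; dn[r] <- dn[r] - h
    fu <- fn(up); fd <- fn(dn)
    if (is.null(fu) || is.null(fd)) {  # one-sided fallback at boundaries
      if (is.null(fu)) { fu <- base; up <- theta }
      if (is.null(fd)) { fd <- base; dn <- theta }
      if (identical(up, dn)) next
    }
    out[, r] <- (fu - fd) / (up[r] - dn[r])
  }
  out[!is.finite(out)] <- 0
  out
}

num_hessian <- function(fn, theta) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  h <- pmax(1e-4 * abs(theta), 1e-5)
  f0 <- fn(theta)
  for (r in seq_len(p)) {
    for (s in r:p) {
      tpp <- theta; tpp[r] <- tpp[r] + h[r]; tpp[s] <- tpp[s] + h[s]
      tpm <- theta; tpm[r] <- tpm[r] + h[r]; tpm[s] <- tpm[s] - h[s]
      tmp <- theta; tmp[r] <- tmp[r] - h[r]; tmp[s] <- tmp[s] + h[s]
      tmm <- theta; tmm[r] <- tmm[r] - h[r]; tmm[s] <- tmm[s] - h[s]
      H[r, s] <- H[s, r] <-
        (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[r] * h[s])
    }
  }
  H
}

# transformed (unconstrained) <-> natural scale
to_unconstrained <- function(theta, order, family) {
  nm <- theta_names(order, family)
  out <- theta
  out[1L] <- log(theta[1L])
  rest <- setdiff(seq_along(nm), 1L)
  out[rest] <- qlogis(pmin(pmax(theta[rest], 1e-8), 1 - 1e-8))
  out
}

to_natural <- function(t, order, family) {
  nm <- theta_names(order, family)
  out <- t
  out[1L] <- exp(t[1L])
  rest <- setdiff(seq_along(nm), 1L)
  out[rest] <- plogis(t[rest])
  names(out) <- nm
  out
}

# ---- exported operations -----------------------------------------------------

#' Negative log-likelihood of an ACD/SACD model
#'
#' Sum of negative log conditional densities over s = 2..N; the first
#' duration conditions the recursion but contributes no term.  Exponential
#' innovations give `sum(log(psi_s) + d_s/psi_s)`; Weibull innovations use
#' the unit-mean density of `d_s/psi_s` divided by `psi_s`.
#'
#' @param params A [sacd_params].
#' @inheritParams conditional_path
#' @return Scalar negative log-likelihood.
#' @export
negative_loglik <- function(params, d, d_review = NULL) {
  stopifnot(inherits(params, "sacd_params"))
  d <- as.numeric(d)
  if (any(d <= 0)) {
    stop_riacd("durations must be positive", "riacd_validation_error")
  }
  order <- implied_order(params)
  rv <- if (order$L_j > 0L)
    as_review_matrix(d_review, length(d), nrow(params$gamma)) else NULL
  theta <- c(params$omega, params$alpha, params$beta,
             if (!is.null(params$gamma)) as.vector(params$gamma),
             if (params$family == "weibull") params$k)
  nll_total(theta, order, params$family, d, rv, params$weights)
}

#' Fit an ACD/SACD model by maximum likelihood
#'
#' Minimizes the conditional negative log-likelihood by quasi-Newton search
#' on transformed parameters (log for omega; logistic into (0, 1) for alpha,
#' beta, gamma and the Weibull shape), from a deterministic default start
#' plus `restarts` seeded random restarts.  Newey-West HAC standard errors,
#' significance stars and a Ljung-Box residual test at `lb_lags` lags are
#' attached.
#'
#' @param d Positive duration series (>= 30 values).
#' @param d_review Reviewed neighbour durations (vector, matrix, list, or
#'   [spatially_reviewed()] pair) when the order has spatial lags.
#' @param order A [sacd_order].
#' @param family Innovation family.
#' @param weights Spatial weights per neighbour (default all 1).
#' @param restarts Number of random restarts beyond the default start.
#' @param start Optional named natural-scale start vector (e.g. a previous
#'   fit's coefficients, used to warm-start the Weibull family from the
#'   exponential optimum).
#' @param nw_bandwidth Bartlett truncation lag; default
#'   `floor(4 * (m/100)^(2/9))` with m the number of likelihood terms.
#' @param lb_lags Ljung-Box lag count.
#' @param restart_seed Seed of the restart jitter stream (the caller's RNG
#'   state is untouched).
#' @return An object of class `acd_fit`.
#' @export
fit_acd <- function(d, d_review = NULL, order = sacd_order(1L, 1L),
                    family = c("exponential", "weibull"), weights = NULL,
                    restarts = 4L, start = NULL, nw_bandwidth = NULL,
                    lb_lags = 10L, restart_seed = 20181102L) {
  family <- match.arg(family)
  stopifnot(inherits(order, "sacd_order"))
  d <- as.numeric(d)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_riacd("durations must be positive and finite", "riacd_validation_error")
  }
  n <- length(d)
  if (n < 30L) {
    stop_riacd("need at least 30 durations to fit", "riacd_insufficient_data_error")
  }
  if (var(d) == 0) {
    stop_riacd("constant durations: degenerate fit", "riacd_degenerate_error")
  }
  J <- length(order$neighbours)
  if (is.null(weights)) weights <- rep(1, J)
  rv <- if (order$L_j > 0L) as_review_matrix(d_review, n, J) else NULL
  nm <- theta_names(order, family)
  npar <- length(nm)
  if (n < 10L * npar) {
    warning(sprintf("only %d durations for %d free parameters", n, npar))
  }

  theta0 <- c(0.1 * mean(d),
              rep(0.1 / max(1L, order$L_d), order$L_d),
              rep(0.6 / max(1L, order$L_psi), order$L_psi),
              rep(0.05 / max(1L, J * order$L_j), J * order$L_j),
              if (family == "weibull") 0.8)
  names(theta0) <- nm
  if (!is.null(start)) {
    for (cn in intersect(names(start), nm)) {
      theta0[cn] <- if (cn == "omega") max(start[[cn]], 1e-8 * mean(d))
                    else min(max(start[[cn]], 1e-6), 1 - 1e-6)
    }
  }
  t0 <- to_unconstrained(theta0, order, family)
  starts <- c(list(t0), with_preserved_seed(restart_seed, function() {
    lapply(seq_len(restarts), function(i) t0 + rnorm(npar, sd = 0.5))
  }))

  obj <- function(t) nll_total(to_natural(t, order, family), order, family,
                               d, rv, weights)
  runs <- lapply(starts, function(s) {
    tryCatch(optim(s, obj, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-9)),
             error = function(e) list(convergence = 99L, value = Inf,
                                      message = conditionMessage(e)))
  })
  ok <- vapply(runs, function(r) identical(r$convergence, 0L) &&
                 is.finite(r$value), logical(1))
  if (!any(ok)) {
    err <- structure(
      class = c("riacd_convergence_error", "riacd_error", "error", "condition"),
      list(message = "no optimizer start converged", call = sys.call(-1),
           diagnostics = runs))
    stop(err)
  }
  best <- runs[ok][[which.min(vapply(runs[ok], `[[`, numeric(1), "value"))]]
  theta_hat <- to_natural(best$par, order, family)
  if (family == "weibull") {
    # the logistic transform cannot reach the admissible boundary k = 1
    # exactly; profile the likelihood there so the exponential model is
    # nested without an optimizer gap
    obj1 <- function(t) nll_total(c(to_natural(t, order, "exponential"), k = 1),
                                  order, "weibull", d, rv, weights)
    r1 <- tryCatch(optim(best$par[seq_len(npar - 1L)], obj1, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-9)),
                   error = function(e) NULL)
    if (!is.null(r1) && identical(r1$convergence, 0L) &&
        r1$value <= best$value) {
      best <- list(par = c(r1$par, qlogis(1 - 1e-10)), value = r1$value,
                   convergence = 0L)
      theta_hat <- c(to_natural(r1$par, order, "exponential"), k = 1)
    }
  }

  contrib_fn <- function(th) nll_contribs(th, order, family, d, rv, weights)
  total_fn <- function(th) nll_total(th, order, family, d, rv, weights)
  S <- num_gradient_matrix(contrib_fn, theta_hat)
  H <- num_hessian(total_fn, theta_hat)
  m <- n - 1L
  B <- nw_bandwidth %||% floor(4 * (m / 100)^(2 / 9))
  se <- hac_sandwich_se(S, H, B)
  names(se) <- nm

  z <- theta_hat / se
  pval <- 2 * pnorm(-abs(z))
  params <- sacd_params(
    omega = theta_hat[["omega"]],
    alpha = theta_hat[grep("^alpha", nm)],
    beta = theta_hat[grep("^beta", nm)],
    gamma = if (J > 0L) matrix(theta_hat[grep("^gamma", nm)], nrow = J),
    family = family, k = if (family == "weibull") theta_hat[["k"]] else 1,
    weights = weights
  )
  path <- conditional_path(params, d, rv)
  boundary <- any(theta_hat[grep("^(alpha|beta|gamma)", nm)] < 1e-5) ||
    (family == "weibull" && theta_hat[["k"]] > 1 - 1e-5)

  structure(list(
    coefficients = theta_hat, se = se, zvalues = z, pvalues = pval,
    stars = star_labels(pval), loglik = -best$value, params = params,
    order = order, family = family, weights = weights,
    path = path, residuals = path$innovations,
    qtest = ljung_box(path$innovations, lags = lb_lags),
    converged = TRUE, n_restarts_used = sum(ok) - 1L,
    boundary = boundary, nw_bandwidth = B,
    d = d, d_review = rv, score_matrix = S, hessian = H, n = n
  ), class = "acd_fit")
}

star_labels <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) "" else if (pp < 0.01) "***"
    else if (pp < 0.05) "**" else if (pp < 0.1) "*" else ""
  }, character(1))
}

hac_sandwich_se <- function(S, H, bandwidth) {
  m <- nrow(S)
  M <- crossprod(S)
  if (bandwidth >= 1L) {
    for (l in seq_len(min(bandwidth, m - 1L))) {
      w <- 1 - l / (bandwidth + 1)
      A <- crossprod(S[(l + 1L):m, , drop = FALSE], S[1L:(m - l), , drop = FALSE])
      M <- M + w * (A + t(A))
    }
  }
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv) || any(!is.finite(Hinv))) {
    warning("singular Hessian; using ridge-regularized inverse")
    lam <- 1e-6 * mean(abs(diag(H)))
    Hinv <- solve(H + diag(lam, nrow(H)))
  }
  V <- Hinv %*% M %*% Hinv
  sqrt(pmax(diag(V), 0))
}

#' Newey-West standard errors of a fitted model
#'
#' Sandwich covariance with inverse-Hessian bread and a Bartlett-weighted
#' HAC kernel (weights `1 - l/(B+1)`) over the per-observation score vectors.
#' `bandwidth = 0` collapses to the plain outer-product sandwich.
#'
#' @param fit An [fit_acd()] result.
#' @param bandwidth Truncation lag B; default the fit's stored bandwidth.
#' @return Named vector of standard errors.
#' @export
newey_west_se <- function(fit, bandwidth = NULL) {
  stopifnot(inherits(fit, "acd_fit"))
  se <- hac_sandwich_se(fit$score_matrix, fit$hessian,
                        bandwidth %||% fit$nw_bandwidth)
  names(se) <- names(fit$coefficients)
  se
}

#' Ljung-Box portmanteau test
#'
#' `Q(L) = N(N+2) sum_k rho^2(k)/(N-k)` on the sample autocorrelations of the
#' standardized innovations, referred to a chi-square with L degrees of
#' freedom.  Insignificance indicates the duration dynamics were captured.
#'
#' @param residuals Standardized innovation sequence.
#' @param lags Number of autocorrelation lags L.
#' @return A `ljung_box` result: list with `lags`, `statistic`, `p_value`,
#'   `autocorrelations`.
#' @export
ljung_box <- function(residuals, lags = 10L) {
  residuals <- as.numeric(residuals)
  N <- length(residuals)
  if (N <= lags) {
    stop_riacd("need more observations than lags", "riacd_insufficient_data_error")
  }
  bt <- Box.test(residuals, lag = lags, type = "Ljung-Box")
  rho <- drop(acf(residuals, lag.max = lags, plot = FALSE)$acf)[-1L]
  structure(list(lags = as.integer(lags),
                 statistic = unname(bt$statistic),
                 p_value = unname(bt$p.value),
                 autocorrelations = rho),
            class = "ljung_box")
}

#' @export
print.ljung_box <- function(x, ...) {
  cat(sprintf("Ljung-Box Q(%d) = %.3f, p = %.3f\n", x$lags, x$statistic,
              x$p_value))
  invisible(x)
}

#' Percentage of significant coefficients across fits
#'
#' Given a collection of fits (e.g. one per station/pollutant series), report
#' per lag (for `beta`) or per neighbour rank (for `gamma`, first spatial
#' lag) the percentage of fits whose coefficient is significant at `level`.
#'
#' @param fits List of [fit_acd()] results.
#' @param coef `"beta"` or `"gamma"`.
#' @param level Two-sided significance level (default 0.05).
#' @return Data frame with columns `term`, `index`, `n_fits`,
#'   `pct_significant`.
#' @export
significance_scan <- function(fits, coef = c("beta", "gamma"), level = 0.05) {
  coef <- match.arg(coef)
  pat <- if (coef == "beta") "^beta([0-9]+)$" else "^gamma([0-9]+)\\.1$"
  rows <- list()
  for (f in fits) {
    nm <- names(f$pvalues)
    hit <- grep(pat, nm, value = TRUE)
    for (h in hit) {
      idx <- as.integer(sub(pat, "\\1", h))
      rows[[length(rows) + 1L]] <-
        data.frame(index = idx, sig = f$pvalues[[h]] < level)
    }
  }
  if (!length(rows)) {
    warning("no matching coefficients found")
    return(data.frame(term = character(), index = integer(),
                      n_fits = integer(), pct_significant = numeric()))
  }
  df <- do.call(rbind, rows)
  agg <- lapply(split(df, df$index), function(g) {
    data.frame(term = coef, index = g$index[1L], n_fits = nrow(g),
               pct_significant = 100 * mean(g$sig))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$index), ]
}

#' @export
print.acd_fit <- function(x, ...) {
  cat(sprintf("RIA-%sACD(%d,%d%s) fit, %s innovations, N = %d\n",
              if (x$order$L_j > 0L) "S" else "", x$order$L_d, x$order$L_psi,
              if (x$order$L_j > 0L) sprintf(",%d", x$order$L_j) else "",
              x$family, x$n))
  tab <- data.frame(estimate = x$coefficients, se = x$se, sig = x$stars)
  print(round_df(tab, 4))
  cat(sprintf("logLik = %.3f; Ljung-Box Q(%d) = %.2f (p = %.2f)%s\n",
              x$loglik, x$qtest$lags, x$qtest$statistic, x$qtest$p_value,
              if (x$boundary) "; boundary estimate(s)" else ""))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' @export
coef.acd_fit <- function(object, ...) object$coefficients

#' @export
logLik.acd_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
summary.acd_fit <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se), z = unname(object$zvalues),
             p = unname(object$pvalues), stars = object$stars,
             row.names = NULL)
}
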
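# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from its definition with naive
# loops, sharing no code with the package internals they check.

# waiting times between threshold exceedances, by double loop over the
# definition min{t - t' : x(t) > q, x(t') > q, t > t'}
oracle_recurrence <- function(x, q) {
  ev <- c()
  for (t in seq_along(x)) {
    if (!is.na(x[t]) && x[t] > q) ev <- c(ev, t)
  }
  dur <- c()
  for (s in seq_along(ev)) {
    if (s == 1L) next
    best <- Inf
    for (r in seq_len(s - 1L)) best <- min(best, ev[s] - ev[r])
    dur <- c(dur, best)
  }
  list(event_times = ev, durations = dur)
}

# naive loop evaluation of the conditional-duration recursion
oracle_conditional_path <- function(omega, alpha, beta, gamma, weights,
                                    d, rv = NULL) {
  n <- length(d)
  m <- mean(d)
  psi <- numeric(n)
  for (s in seq_len(n)) {
    p <- omega
    for (u in seq_along(alpha)) {
      p <- p + alpha[u] * if (s - u >= 1L) d[s - u] else m
    }
    for (v in seq_along(beta)) {
      p <- p + beta[v] * if (s - v >= 1L) psi[s - v] else m
    }
    if (!is.null(gamma)) {
      for (j in seq_len(nrow(gamma))) {
        for (k in seq_len(ncol(gamma))) {
          val <- if (s - k >= 1L) rv[s - k, j] else m
          p <- p + gamma[j, k] * weights[j] * val
        }
      }
    }
    psi[s] <- p
  }
  psi
}

# product-form likelihood: multiply conditional densities, then -log
oracle_nll <- function(psi, d, family, k = 1) {
  lik <- 1
  for (s in 2:length(d)) {
    f <- if (family == "exponential") {
      (1 / psi[s]) * exp(-d[s] / psi[s])
    } else {
      G <- gamma(1 + 1 / k)
      eps <- d[s] / psi[s]
      (1 / psi[s]) * k * G * (eps * G)^(k - 1) * exp(-(eps * G)^k)
    }
    lik <- lik * f
  }
  -log(lik)
}

# spherical law of cosines great-circle distance, km
oracle_sloc_km <- function(lon1, lat1, lon2, lat2, R = 6371) {
  rad <- pi / 180
  a <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  R * acos(pmin(pmax(a, -1), 1))
}

# textbook Ljung-Box from first principles
oracle_ljung_box <- function(x, L) {
  N <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  rho <- vapply(seq_len(L), function(k) {
    sum(xc[(k + 1):N] * xc[1:(N - k)]) / denom
  }, numeric(1))
  Q <- N * (N + 2) * sum(rho^2 / (N - seq_len(L)))
  list(Q = Q, p = pchisq(Q, df = L, lower.tail = FALSE), rho = rho)
}

# fractional Gaussian noise via Davies-Harte circulant embedding
oracle_fgn <- function(n, H, seed = 1) {
  set.seed(seed)
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  r <- g(0:(n - 1))
  circ <- c(r, 0, rev(r[-1]))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0
  m <- length(circ)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  w <- fft(sqrt(lambda / (2 * m)) * z)
  Re(w)[seq_len(n)]
}

# small random hourly series with gaps, for adjustment property tests
random_hourly <- function(n_days = 6, miss_frac = 0.1, seed = 1) {
  set.seed(seed)
  v <- rexp(n_days * 24, rate = 1 / 10) + 0.5
  v[sample(length(v), floor(miss_frac * length(v)))] <- NA
  hourly_series("s1", "PM2.5", as.POSIXct("2015-03-01 00:00:00", tz = "UTC"), v)
}
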
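#' Model order of an ACD/SACD specification
#'
#' @param L_d Number of duration lags (alpha terms).
#' @param L_psi Number of conditional-duration lags (beta terms).
#' @param L_j Number of spatial lags (gamma terms); requires `neighbours`.
#' @param neighbours Ordered character vector of neighbour identifiers
#'   (nearest first); may be empty when `L_j = 0`.
#' @return A `sacd_order` object.
#' @export
sacd_order <- function(L_d = 1L, L_psi = 1L, L_j = 0L, neighbours = character()) {
  if (!is_count(L_d) || !is_count(L_psi) || !is_count(L_j)) {
    stop_riacd("orders must be non-negative integers", "riacd_validation_error")
  }
  if (L_j > 0L && length(neighbours) == 0L) {
    stop_riacd("spatial lags require at least one neighbour", "riacd_validation_error")
  }
  structure(list(L_d = as.integer(L_d), L_psi = as.integer(L_psi),
                 L_j = as.integer(L_j),
                 neighbours = as.character(neighbours)),
            class = "sacd_order")
}

#' @export
print.sacd_order <- function(x, ...) {
  cat(sprintf("<sacd_order> (%d,%d,%d)%s\n", x$L_d, x$L_psi, x$L_j,
              if (length(x$neighbours))
                paste0(", neighbours: ", paste(x$neighbours, collapse = ", "))
              else ""))
  invisible(x)
}

#' Parameters of an ACD/SACD model
#'
#' All coefficients are non-negative (with `omega > 0`) so the conditional
#' duration recursion stays positive.  The Weibull shape is confined to
#' (0, 1] -- decreasing densities, nesting the exponential at `k = 1` -- and
#' its scale is always the unit-mean value `1/gamma(1 + 1/k)`.
#'
#' @param omega Intercept, > 0 (units of the duration series).
#' @param alpha Coefficients on lagged durations (length `L_d`).
#' @param beta Coefficients on lagged conditional durations (length `L_psi`).
#' @param gamma Spatial coefficients: `J x L_j` matrix (neighbour by spatial
#'   lag), or a vector/scalar for a single neighbour.  `NULL` for a pure ACD.
#' @param family `"exponential"` or `"weibull"` innovation law.
#' @param k Weibull shape in (0, 1]; ignored for the exponential family.
#' @param weights Non-negative spatial weights, one per neighbour (default
#'   all 1, the adjacency setting; pass 1/distance values for a deterrence
#'   weighting).
#' @return A `sacd_params` object.
#' @export
sacd_params <- function(omega, alpha = numeric(), beta = numeric(),
                        gamma = NULL, family = c("exponential", "weibull"),
                        k = 1, weights = NULL) {
  family <- match.arg(family)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop_riacd("'omega' must be a positive scalar", "riacd_validation_error")
  }
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (any(alpha < 0) || any(beta < 0)) {
    stop_riacd("'alpha' and 'beta' must be non-negative", "riacd_validation_error")
  }
  if (!is.null(gamma)) {
    if (!is.matrix(gamma)) gamma <- matrix(as.numeric(gamma), nrow = 1L)
    if (any(gamma < 0)) {
      stop_riacd("'gamma' must be non-negative", "riacd_validation_error")
    }
    if (length(gamma) == 0L) gamma <- NULL
  }
  if (family == "weibull" && (k <= 0 || k > 1)) {
    stop_riacd("Weibull shape 'k' must lie in (0, 1]", "riacd_validation_error")
  }
  J <- if (is.null(gamma)) 0L else nrow(gamma)
  if (is.null(weights)) weights <- rep(1, J)
  if (length(weights) != J || any(weights < 0)) {
    stop_riacd("'weights' must be non-negative, one per neighbour",
               "riacd_validation_error")
  }
  structure(list(omega = omega, alpha = alpha, beta = beta, gamma = gamma,
                 family = family, k = if (family == "weibull") k else 1,
                 weights = weights),
            class = "sacd_params")
}

#' @export
print.sacd_params <- function(x, ...) {
  cat(sprintf("<sacd_params> %s%s: omega = %.4g", x$family,
              if (x$family == "weibull") sprintf(" (k = %.3g)", x$k) else "",
              x$omega))
  if (length(x$alpha)) cat(", alpha =", paste(signif(x$alpha, 4), collapse = " "))
  if (length(x$beta)) cat(", beta =", paste(signif(x$beta, 4), collapse = " "))
  if (!is.null(x$gamma)) cat(", gamma =", paste(signif(x$gamma, 4), collapse = " "))
  cat("\n")
  invisible(x)
}

implied_order <- function(params) {
  sacd_order(length(params$alpha), length(params$beta),
             if (is.null(params$gamma)) 0L else ncol(params$gamma),
             neighbours = if (is.null(params$gamma)) character()
                          else paste0("j", seq_len(nrow(params$gamma))))
}

as_review_matrix <- function(d_review, n, J) {
  if (J == 0L) return(NULL)
  if (is.null(d_review)) {
    stop_riacd("spatial terms need reviewed durations 'd_review'",
               "riacd_validation_error")
  }
  if (inherits(d_review, "spatial_review_pair")) d_review <- d_review$reviewed
  if (is.list(d_review) && !is.data.frame(d_review)) {
    d_review <- do.call(cbind, d_review)
  }
  if (!is.matrix(d_review)) d_review <- matrix(d_review, ncol = 1L)
  if (nrow(d_review) != n || ncol(d_review) != J) {
    stop_riacd("'d_review' must align with the duration series (one column per neighbour)",
               "riacd_validation_error")
  }
  d_review
}

#' Conditional-duration path of an ACD/SACD model
#'
#' Evaluates the recursion
#' `psi_s = omega + sum_u alpha_u d_{s-u} + sum_v beta_v psi_{s-v}
#'  + sum_k sum_j gamma_{j,k} w_j d_review_j[s-k]`
#' over a duration series.  All pre-sample values of `d`, `psi` and
#' `d_review` are set to the sample mean of `d`.
#'
#' @param params A [sacd_params].
#' @param d Positive duration series.
#' @param d_review Reviewed durations: vector, `n x J` matrix, list of
#'   vectors, or a [spatially_reviewed()] pair; `NULL` for a pure ACD.
#' @return A `conditional_path`: list with `psi` (all > 0) and `innovations`
#'   `= d/psi` (unit mean under correct specification).
#' @export
conditional_path <- function(params, d, d_review = NULL) {
  stopifnot(inherits(params, "sacd_params"))
  d <- as.numeric(d)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_riacd("durations must be positive and finite", "riacd_validation_error")
  }
  n <- length(d)
  m <- mean(d)
  ord <- implied_order(params)
  z <- rep(params$omega, n)
  for (u in seq_len(ord$L_d)) {
    z <- z + params$alpha[u] * c(rep(m, u), d)[seq_len(n)]
  }
  if (ord$L_j > 0L) {
    rv <- as_review_matrix(d_review, n, nrow(params$gamma))
    for (j in seq_len(nrow(params$gamma))) {
      for (k in seq_len(ord$L_j)) {
        z <- z + params$gamma[j, k] * params$weights[j] *
          c(rep(m, k), rv[, j])[seq_len(n)]
      }
    }
  }
  psi <- if (ord$L_psi > 0L) {
    as.numeric(filter(z, params$beta, method = "recursive",
                      init = rep(m, ord$L_psi)))
  } else {
    z
  }
  structure(list(psi = psi, innovations = d / psi), class = "conditional_path")
}

#' Stationary expected duration
#'
#' For an uncoupled model the long-run mean is `omega / (1 - sum(alpha) -
#' sum(beta))`.  For two mutually nearest-neighbour (1,1,1) stations the
#' coupled expectation for station i is
#' `(omega_j gamma_i + omega_i (1 - alpha_j - beta_j)) /
#'  ((1 - alpha_i - beta_i)(1 - alpha_j - beta_j) - gamma_i gamma_j)`,
#' which reduces to the uncoupled form when `gamma_i = gamma_j = 0` and to
#' `mu_i + mu_j gamma_i / (1 - alpha_i - beta_i)` when only `gamma_j = 0`.
#'
#' @param params_i [sacd_params] of the station of interest.
#' @param params_j Optional [sacd_params] of its coupled partner.
#' @return Expected duration (same units as the durations).
#' @export
stationary_mean <- function(params_i, params_j = NULL) {
  stopifnot(inherits(params_i, "sacd_params"))
  ab_i <- sum(params_i$alpha) + sum(params_i$beta)
  g_i <- if (is.null(params_i$gamma)) 0 else
    sum(params_i$gamma[, 1L] * params_i$weights)
  if (is.null(params_j)) {
    if (g_i != 0) {
      stop_riacd("coupled model: supply the partner's parameters",
                 "riacd_validation_error")
    }
    if (ab_i >= 1) {
      stop_riacd("nonstationary: alpha + beta >= 1", "riacd_nonstationary_error")
    }
    return(params_i$omega / (1 - ab_i))
  }
  stopifnot(inherits(params_j, "sacd_params"))
  ab_j <- sum(params_j$alpha) + sum(params_j$beta)
  g_j <- if (is.null(params_j$gamma)) 0 else
    sum(params_j$gamma[, 1L] * params_j$weights)
  den <- (1 - ab_i) * (1 - ab_j) - g_i * g_j
  if (den <= 0) {
    stop_riacd("nonstationary coupled system (denominator <= 0)",
               "riacd_nonstationary_error")
  }
  (params_j$omega * g_i + params_i$omega * (1 - ab_j)) / den
}

#' Unit-mean Weibull scale
#'
#' The scale `lambda = 1/gamma(1 + 1/k)` that gives a Weibull(`k`, `lambda`)
#' variate mean exactly 1.
#'
#' @param k Shape in (0, 1].
#' @return The scale `lambda`.
#' @export
unit_weibull_scale <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1) {
    stop_riacd("'k' must lie in (0, 1]", "riacd_domain_error")
  }
  1 / gamma(1 + 1 / k)
}

#' Density of the unit-mean innovation law
#'
#' Exponential: `exp(-eps)`.  Weibull: the Weibull(`k`, `1/gamma(1+1/k)`)
#' density, which has mean 1 by construction and equals the exponential at
#' `k = 1`.
#'
#' @param eps Positive evaluation points.
#' @param family `"exponential"` or `"weibull"`.
#' @param k Weibull shape in (0, 1].
#' @param log Return log density?
#' @return Density values.
#' @export
innovation_density <- function(eps, family = c("exponential", "weibull"),
                               k = 1, log = FALSE) {
  family <- match.arg(family)
  if (any(eps <= 0)) {
    stop_riacd("innovations must be positive", "riacd_domain_error")
  }
  if (family == "exponential") {
    return(if (log) -eps else exp(-eps))
  }
  dweibull(eps, shape = k, scale = unit_weibull_scale(k), log = log)
}
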
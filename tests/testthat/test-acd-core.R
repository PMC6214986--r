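test_that("conditional path collapses and matches hand recursion", {
  # no dynamics: psi is constant at omega
  p0 <- sacd_params(0.7)
  expect_equal(conditional_path(p0, c(1, 2, 3))$psi, rep(0.7, 3))

  # hand-computed ACD(1,1) with mean initialization
  p <- sacd_params(0.5, alpha = 0.2, beta = 0.3)
  cp <- conditional_path(p, c(1, 2))
  expect_equal(cp$psi, c(1.25, 1.075))
  expect_equal(cp$innovations, c(1, 2) / c(1.25, 1.075))

  expect_error(conditional_path(p, c(1, -1)), class = "riacd_validation_error")
})

test_that("conditional path equals the naive loop oracle for random models", {
  set.seed(13)
  for (i in 1:100) {
    Ld <- sample(0:3, 1); Lp <- sample(0:3, 1)
    Lj <- sample(0:2, 1); J <- if (Lj > 0) sample(1:2, 1) else 0
    n <- sample(10:60, 1)
    d <- rexp(n) + 0.1
    omega <- runif(1, 0.05, 1)
    alpha <- runif(Ld, 0, 0.3)
    beta <- runif(Lp, 0, 0.3)
    gamma <- if (Lj > 0) matrix(runif(J * Lj, 0, 0.2), nrow = J)
    w <- if (Lj > 0) runif(J, 0.5, 1.5)
    rv <- if (Lj > 0) matrix(rexp(n * J) + 0.1, n, J)
    p <- sacd_params(omega, alpha, beta, gamma, weights = w)
    got <- conditional_path(p, d, rv)$psi
    want <- oracle_conditional_path(omega, alpha, beta, gamma, w, d, rv)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0))
  }
})

test_that("spatial path with gamma = 0 coincides with the pure ACD path", {
  set.seed(14)
  d <- rexp(200) + 0.1
  rv <- matrix(rexp(200) + 0.1, ncol = 1)
  p_acd <- sacd_params(0.3, 0.15, 0.5)
  p_sacd <- sacd_params(0.3, 0.15, 0.5, gamma = 1e-300)
  expect_equal(conditional_path(p_sacd, d, rv)$psi,
               conditional_path(p_acd, d)$psi, tolerance = 1e-12)
})

test_that("stationary means follow the coupled and uncoupled expectations", {
  # worked numbers: omega/(1 - alpha - beta) with the published coefficients
  expect_equal(round(stationary_mean(sacd_params(0.31, 0.26, 0.46)), 2), 1.11)

  # coupled formula reduces to the uncoupled one when both gammas vanish
  pi_ <- sacd_params(0.2, 0.1, 0.3, gamma = 1e-300)
  pj_ <- sacd_params(0.4, 0.2, 0.2, gamma = 1e-300)
  expect_equal(stationary_mean(pi_, pj_),
               stationary_mean(sacd_params(0.2, 0.1, 0.3)), tolerance = 1e-12)

  # one-way coupling: mu_i + mu_j * gamma_i / (1 - alpha_i - beta_i)
  pi1 <- sacd_params(0.2, 0.1, 0.3, gamma = 0.25)
  pj0 <- sacd_params(0.4, 0.2, 0.2, gamma = 1e-300)
  mu_i <- 0.2 / 0.6; mu_j <- 0.4 / 0.6
  expect_equal(stationary_mean(pi1, pj0), mu_i + mu_j * 0.25 / 0.6,
               tolerance = 1e-9)

  # symmetric coupling matches the fixed point of the two-line expectation map
  ps <- sacd_params(0.2, 0.1, 0.3, gamma = 0.2)
  mu <- c(1, 1)
  for (it in 1:2000) {
    mu <- c(0.2 + 0.1 * mu[1] + 0.3 * mu[1] + 0.2 * mu[2],
            0.2 + 0.1 * mu[2] + 0.3 * mu[2] + 0.2 * mu[1])
  }
  expect_equal(stationary_mean(ps, ps), mu[1], tolerance = 1e-10)

  expect_error(stationary_mean(sacd_params(0.1, 0.5, 0.5)),
               class = "riacd_nonstationary_error")
  expect_error(stationary_mean(sacd_params(0.1, 0.4, 0.4, gamma = 0.5),
                               sacd_params(0.1, 0.4, 0.4, gamma = 0.5)),
               class = "riacd_nonstationary_error")
})

test_that("unit-mean Weibull scale and densities behave", {
  expect_equal(unit_weibull_scale(1), 1)
  expect_equal(unit_weibull_scale(0.5), 0.5)
  expect_error(unit_weibull_scale(1.2), class = "riacd_domain_error")
  expect_error(unit_weibull_scale(0), class = "riacd_domain_error")

  # Monte Carlo unit mean at k = 0.7
  set.seed(15)
  draws <- rweibull(1e6, shape = 0.7, scale = unit_weibull_scale(0.7))
  expect_lt(abs(mean(draws) - 1), 3 * sd(draws) / sqrt(1e6))

  # exponential density and the k = 1 Weibull coincide
  eps <- c(1e-8, 0.3, 1, 4)
  expect_equal(innovation_density(eps, "weibull", k = 1),
               innovation_density(eps, "exponential"), tolerance = 1e-14)
  expect_equal(innovation_density(1e-12, "exponential"), 1, tolerance = 1e-10)
  expect_error(innovation_density(-1, "exponential"),
               class = "riacd_domain_error")

  # each family is a valid unit-mean density (quadrature)
  for (k in c(0.4, 0.7, 1)) {
    mass <- integrate(function(e) innovation_density(e, "weibull", k),
                      0, Inf, rel.tol = 1e-9)$value
    m1 <- integrate(function(e) e * innovation_density(e, "weibull", k),
                    0, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    expect_equal(m1, 1, tolerance = 1e-6)
  }
})

test_that("long simulated paths reach the stationary mean", {
  p <- sacd_params(0.1, 0.1, 0.8)
  sim <- simulate_acd(p, 1e5, seed = 99)
  expect_lt(abs(mean(sim$d) - stationary_mean(p)) / stationary_mean(p), 0.02)
})

test_that("model specification JSON round-trips losslessly", {
  ord <- sacd_order(2, 1, 1, neighbours = "7")
  par <- sacd_params(0.37, c(0.1, 0.05), 0.6, gamma = 0.07,
                     family = "weibull", k = 0.55, weights = 2)
  f <- tempfile(fileext = ".json")
  write_model_json(ord, "weibull", f, params = par)
  back <- read_model_json(f)
  expect_equal(back$order, ord)
  expect_equal(back$family, "weibull")
  expect_equal(back$params$omega, par$omega)
  expect_equal(back$params$alpha, par$alpha)
  expect_equal(back$params$gamma, par$gamma)
  expect_equal(back$params$k, par$k)
  expect_equal(back$params$weights, par$weights)
})
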
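test_that("negative log-likelihood matches direct substitution and nesting", {
  # single contributing step with psi = 1: contribution log(1) + 1/1 = 1
  p <- sacd_params(1)
  expect_equal(negative_loglik(p, c(1, 1)), 1)

  # Weibull at k = 1 equals the exponential likelihood
  set.seed(51)
  for (i in 1:10) {
    d <- rexp(50) + 0.05
    pe <- sacd_params(0.3, 0.2, 0.4)
    pw <- sacd_params(0.3, 0.2, 0.4, family = "weibull", k = 1)
    expect_equal(negative_loglik(pw, d), negative_loglik(pe, d),
                 tolerance = 1e-10)
  }
})

test_that("likelihood equals the product-form oracle on random instances", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    d <- rexp(n) + 0.05
    fam <- sample(c("exponential", "weibull"), 1)
    k <- runif(1, 0.3, 1)
    use_spatial <- runif(1) < 0.4
    rv <- if (use_spatial) matrix(rexp(n) + 0.05, ncol = 1)
    p <- sacd_params(runif(1, 0.05, 0.5), runif(1, 0, 0.3), runif(1, 0, 0.4),
                     gamma = if (use_spatial) runif(1, 0, 0.2),
                     family = fam, k = k)
    psi <- conditional_path(p, d, rv)$psi
    expect_equal(negative_loglik(p, d, rv),
                 oracle_nll(psi, d, fam, k), tolerance = 1e-10)
  }
})

test_that("the fitted optimum is never beaten by the truth, and the Weibull
           fit never loses to the nested exponential fit", {
  set.seed(53)
  truth <- sacd_params(0.1, 0.1, 0.8)
  for (i in 1:5) {
    sim <- simulate_acd(truth, 800)
    f_exp <- fit_acd(sim$d, restarts = 1)
    expect_lte(-f_exp$loglik, negative_loglik(truth, sim$d) + 1e-6)
    f_wei <- fit_acd(sim$d, family = "weibull", restarts = 1,
                     start = coef(f_exp))
    expect_lte(-f_wei$loglik, -f_exp$loglik + 1e-4)
  }
})

test_that("fit recovers simulated parameters and flags degenerate input", {
  set.seed(54)
  sim <- simulate_acd(sacd_params(0.1, 0.1, 0.8), 3000)
  f <- fit_acd(sim$d)
  expect_true(f$converged)
  expect_lt(abs(coef(f)[["alpha1"]] - 0.1), 0.08)
  expect_lt(abs(coef(f)[["beta1"]] - 0.8), 0.15)
  expect_equal(mean(f$residuals), 1, tolerance = 0.05)
  expect_true(all(f$se > 0))
  # stars consistent with |z| against normal critical values
  sig2 <- abs(f$zvalues) > qnorm(0.975)
  expect_identical(unname(f$stars %in% c("**", "***")), unname(sig2))

  expect_error(fit_acd(rep(1, 100)), class = "riacd_degenerate_error")
  expect_error(fit_acd(rexp(10) + 1), class = "riacd_insufficient_data_error")
})

test_that("HAC standard errors collapse, agree, and inflate as expected", {
  set.seed(55)
  sim <- simulate_acd(sacd_params(0.2, 0.15, 0.6), 1500)
  f <- fit_acd(sim$d)

  # bandwidth 0 equals the plain outer-product sandwich
  se0 <- newey_west_se(f, bandwidth = 0)
  S <- f$score_matrix; H <- f$hessian
  Hinv <- solve(H)
  V0 <- Hinv %*% crossprod(S) %*% Hinv
  expect_equal(unname(se0), sqrt(diag(V0)), tolerance = 1e-12)

  # correctly specified model: serially uncorrelated scores, so HAC SEs sit
  # near the inverse-Hessian SEs
  se_hac <- newey_west_se(f)
  se_hess <- sqrt(diag(Hinv))
  expect_true(all(abs(se_hac / se_hess - 1) < 0.25))

  # positively autocorrelated scores inflate HAC variance on average
  set.seed(56)
  wins <- vapply(1:50, function(i) {
    s_ar <- as.numeric(filter(rnorm(400), 0.6, method = "recursive"))
    S1 <- cbind(s_ar, as.numeric(filter(rnorm(400), 0.6, method = "recursive")))
    H1 <- diag(2)
    hac <- riacd:::hac_sandwich_se(S1, H1, bandwidth = 8)
    naive <- riacd:::hac_sandwich_se(S1, H1, bandwidth = 0)
    mean(hac) > mean(naive)
  }, logical(1))
  expect_gt(mean(wins), 0.8)
})

test_that("Ljung-Box matches a first-principles oracle and the chi-square law", {
  set.seed(57)
  for (i in 1:100) {
    x <- rexp(sample(50:200, 1))
    L <- sample(3:12, 1)
    got <- ljung_box(x, lags = L)
    want <- oracle_ljung_box(x, L)
    expect_equal(got$statistic, want$Q, tolerance = 1e-8)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
    expect_equal(got$autocorrelations, want$rho, tolerance = 1e-8)
  }

  # fixed 20-point hand case pinned to the oracle
  x20 <- c(3.1, 0.4, 2.2, 1.8, 0.9, 5.0, 0.2, 1.1, 2.7, 0.6,
           1.4, 3.3, 0.8, 2.0, 1.2, 0.5, 4.1, 1.6, 0.3, 2.5)
  got <- ljung_box(x20, lags = 2)
  want <- oracle_ljung_box(x20, 2)
  expect_equal(got$statistic, want$Q, tolerance = 1e-10)

  expect_error(ljung_box(rexp(5), lags = 10),
               class = "riacd_insufficient_data_error")
})

test_that("residuals of a correctly specified fit pass the Ljung-Box test at
           roughly the nominal rate", {
  set.seed(58)
  pass <- vapply(1:60, function(i) {
    sim <- simulate_acd(sacd_params(0.1, 0.1, 0.8), 700)
    f <- fit_acd(sim$d, restarts = 0)
    f$qtest$p_value > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.85)
})

test_that("significance scan reports the fraction of significant coefficients", {
  fake_fit <- function(pv) {
    structure(list(pvalues = pv), class = "acd_fit")
  }
  all_sig <- replicate(10, fake_fit(c(omega = 0.001, alpha1 = 0.001,
                                      beta1 = 0.001, beta2 = 0.001,
                                      `gamma1.1` = 0.001)), simplify = FALSE)
  sc <- significance_scan(all_sig, coef = "beta")
  expect_equal(sc$pct_significant, c(100, 100))
  expect_equal(sc$index, c(1, 2))
  sg <- significance_scan(all_sig, coef = "gamma")
  expect_equal(sg$pct_significant, 100)

  # planted mixture: 30% significant gamma
  mix <- c(replicate(3, fake_fit(c(`gamma1.1` = 0.001)), simplify = FALSE),
           replicate(7, fake_fit(c(`gamma1.1` = 0.8)), simplify = FALSE))
  expect_equal(significance_scan(mix, coef = "gamma")$pct_significant, 30)

  expect_warning(significance_scan(list(fake_fit(c(omega = 0.5))), "beta"))
})
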
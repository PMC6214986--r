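test_that("recurrence extraction matches the definition on hand cases", {
  expect_length(extract_recurrence(c(0.5, 0.5, 0.5), 2)$durations, 0L)
  expect_true(extract_recurrence(c(0.5, 0.5, 0.5), 2)$too_few)

  rec <- extract_recurrence(c(3, 1, 3, 3), 2)
  expect_equal(rec$event_times, c(1L, 3L, 4L))
  expect_equal(rec$durations, c(2, 1))
  expect_equal(rec$mean_duration, 1.5)

  all_over <- extract_recurrence(rep(5, 20), 2)
  expect_true(all(all_over$durations == 1))
  expect_error(extract_recurrence(c(1, 2), 0), class = "riacd_validation_error")
})

test_that("recurrence extraction agrees with the brute-force double-loop oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    x <- rexp(n)
    x[sample(n, floor(0.1 * n))] <- NA
    q <- runif(1, 0.5, 3)
    got <- extract_recurrence(x, q)
    want <- oracle_recurrence(x, q)
    expect_equal(got$event_times, as.integer(want$event_times))
    expect_equal(got$durations, as.numeric(want$durations))
    # durations telescope to the full span
    if (length(got$durations)) {
      expect_equal(sum(got$durations),
                   got$event_times[length(got$event_times)] - got$event_times[1])
    }
  }
})

test_that("exceedance probability matches the reciprocal mean interval", {
  # i.i.d. uniform: both sides estimate P(x > q) = 0.1
  set.seed(5)
  x <- runif(1e5)
  chk <- exceedance_check(x, 0.9)
  se <- 3 * sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(chk$p_exceed - 0.1), se)
  expect_lt(abs(chk$recip_mean_interval - 0.1), se + 0.01)

  # everything above threshold
  chk2 <- exceedance_check(rep(5, 50), 2)
  expect_equal(chk2$p_exceed, 1)
  expect_equal(chk2$recip_mean_interval, 1)

  # counting identity on a strongly clustered series: 1/<d> equals
  # (events - 1) / observed span regardless of clustering
  set.seed(6)
  x <- as.numeric(filter(rnorm(5000), 0.95, method = "recursive"))
  rec <- extract_recurrence(x, 2)
  span <- diff(range(rec$event_times))
  expect_equal(1 / rec$mean_duration, (length(rec$event_times) - 1) / span)

  expect_error(exceedance_check(c(3, 1, 1), 2),
               class = "riacd_insufficient_data_error")
})

test_that("spatial review picks the most recent completed neighbour interval", {
  # hand-built toy: i events at (3, 6, 10); j events at (2, 5, 9)
  x_i <- rep(0, 12); x_i[c(3, 6, 10)] <- 5
  x_j <- rep(0, 12); x_j[c(2, 5, 9)] <- 5
  ri <- extract_recurrence(x_i, 2)
  rj <- extract_recurrence(x_j, 2)
  pair <- spatially_reviewed(ri, rj)
  expect_equal(ri$durations, c(3, 4))
  expect_equal(pair$reviewed, c(3, 4))
  expect_equal(pair$n_filled, 0L)

  # identical series: reviewed equals own durations exactly
  set.seed(7)
  x <- rexp(2000)
  r <- extract_recurrence(x, 1.5)
  same <- spatially_reviewed(r, r)
  expect_identical(same$reviewed, r$durations)

  # i's first interval completes before any of j's: mean-interval fill
  y_i <- rep(0, 30); y_i[c(1, 3, 20)] <- 5
  y_j <- rep(0, 30); y_j[c(10, 14, 25)] <- 5
  pj <- extract_recurrence(y_j, 2)
  pf <- spatially_reviewed(extract_recurrence(y_i, 2), pj)
  expect_equal(pf$reviewed[1], mean(pj$durations))
  expect_equal(pf$n_filled, 1L)

  # neighbour with no completed intervals: flagged all-fill
  z_j <- rep(0, 30); z_j[4] <- 5
  pz <- spatially_reviewed(extract_recurrence(y_i, 2), extract_recurrence(z_j, 2))
  expect_true(pz$all_fill)
  expect_length(pz$reviewed, 2L)

  # mismatched thresholds
  expect_error(spatially_reviewed(extract_recurrence(x, 1.5),
                                  extract_recurrence(x, 2)),
               class = "riacd_config_error")
})

test_that("AR lag scan has near-nominal size and detects real dependence", {
  # null: i.i.d. exponential durations.  Ten independent 5% coefficient
  # tests leave all lags insignificant with probability 0.95^10 = 0.60;
  # allow 3 binomial SEs around that over 200 replicates.
  set.seed(21)
  null_zero <- vapply(1:200, function(i) {
    ar_max_significant_lag(rexp(500), max_lag = 10) == 0L
  }, logical(1))
  expect_lt(abs(mean(null_zero) - 0.95^10), 3 * sqrt(0.6 * 0.4 / 200))

  # power: AR(1) with coefficient 0.8 -> L >= 1 essentially always
  set.seed(22)
  power <- vapply(1:50, function(i) {
    d <- as.numeric(filter(rnorm(2000), 0.8, method = "recursive")) + 20
    ar_max_significant_lag(d, max_lag = 10) >= 1L
  }, logical(1))
  expect_gte(mean(power), 0.95)

  expect_error(ar_max_significant_lag(rexp(15), max_lag = 10),
               class = "riacd_insufficient_data_error")
})

test_that("DFA Hurst estimates recover known exponents", {
  set.seed(31)
  h_white <- hurst_exponent(rnorm(1e4))
  expect_lt(abs(h_white$H - 0.5), 0.05)
  expect_true(is.finite(h_white$se))

  h_fgn <- hurst_exponent(oracle_fgn(2^14, H = 0.8, seed = 3))
  expect_gt(h_fgn$H, 0.7)
  expect_lt(h_fgn$H, 0.9)

  expect_error(hurst_exponent(rnorm(50)),
               class = "riacd_insufficient_data_error")
})

test_that("scaling_report summarizes per-threshold structure", {
  set.seed(41)
  net <- simulate_network(2, 6000, seed = 41)
  adj <- diurnal_adjust(net$series[[1]])
  rep_tab <- scaling_report(adj, thresholds = c(1.5, 2, 6))
  expect_equal(rep_tab$q, c(1.5, 2, 6))
  expect_true(all(rep_tab$n_events >= 0))
  # very high threshold: too few events for the estimators
  expect_true(is.na(rep_tab$L[3]) || rep_tab$n_events[3] > 20)
})
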
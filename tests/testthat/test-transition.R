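test_that("marker-fraction equilibria reproduce the two cell-line estimates", {
  # luminal line: CD44+CD24- 0.8%, ALDH+ 0.3%
  eq_luminal <- equilibrium_from_marker_fractions(0.008, 0.003)
  expect_equal(round(eq_luminal$pi_emt, 2), 0.73)
  # triple-negative line: 1% tumor-initiating vs 4% ALDH+
  eq_tn <- equilibrium_from_marker_fractions(0.01, 0.04)
  expect_equal(eq_tn$pi_emt, 0.2)
  expect_equal(eq_tn$pi_met, 0.8)
  # symmetry and exact normalization
  eq_sym <- equilibrium_from_marker_fractions(0.37, 0.37)
  expect_equal(eq_sym$pi_emt, 0.5)
  expect_identical(eq_sym$pi_emt + eq_sym$pi_met, 1)
  expect_error(equilibrium_from_marker_fractions(0, 0), "positive")
})

test_that("met_fraction_from_rates evaluates lambda_met / (lambda_emt + lambda_met)", {
  expect_equal(met_fraction_from_rates(transition_rates(0.02, 0.08)), 0.8)
  expect_equal(met_fraction_from_rates(transition_rates(0.3, 0.3)), 0.5)
  expect_equal(met_fraction_from_rates(transition_rates(0.46, 0.08)),
               0.08 / 0.54)
  expect_equal(round(met_fraction_from_rates(transition_rates(0.46, 0.08)), 3),
               0.148)
})

test_that("complete_rates solves detailed balance in both directions", {
  eq <- equilibrium_distribution(0.2)
  r1 <- complete_rates(eq, lambda_met = 0.08)
  expect_equal(r1$lambda_emt, 0.02)
  r2 <- complete_rates(equilibrium_distribution(0.5), lambda_met = 0.1)
  expect_equal(r2$lambda_emt, 0.1)
  r3 <- complete_rates(eq, lambda_emt = 0.02)
  expect_equal(r3$lambda_met, 0.08)
  expect_error(complete_rates(eq), "exactly one")
  expect_error(complete_rates(eq, lambda_emt = 1, lambda_met = 1),
               "exactly one")
  expect_error(complete_rates(equilibrium_distribution(0),
                              lambda_met = 0.08), "degenerate")
})

test_that("detailed balance holds to 1e-12 and round-trips the equilibrium", {
  set.seed(31)
  for (i in 1:25) {
    pi_emt <- runif(1, 0.01, 0.99)
    lam <- runif(1, 1e-4, 2)
    eq <- equilibrium_distribution(pi_emt)
    r <- complete_rates(eq, lambda_met = lam)
    # stationary flux balance pi_EMT * lambda_MET = pi_MET * lambda_EMT
    expect_equal(eq$pi_emt * r$lambda_met, eq$pi_met * r$lambda_emt,
                 tolerance = 1e-12)
    expect_equal(met_fraction_from_rates(r), eq$pi_met, tolerance = 1e-12)
  }
})

test_that("log-linear fit recovers exact exponential rates", {
  t <- seq(0, 40, length.out = 15)
  decay <- list(times = t, values = exp(-0.08 * t))
  expect_equal(fit_exponential_rate(decay, "decay")$rate, 0.08,
               tolerance = 1e-12)
  rise <- list(times = t, values = exp(0.46 * t))
  expect_equal(fit_exponential_rate(rise, "rise")$rate, 0.46,
               tolerance = 1e-12)
  flat <- list(times = t, values = rep(2.5, length(t)))
  expect_equal(fit_exponential_rate(flat, "decay")$rate, 0)
  expect_error(fit_exponential_rate(list(times = 1:2, values = c(1, 2))),
               "3 points")
  expect_error(
    fit_exponential_rate(list(times = 1:5, values = c(1, 2, -1, 2, 1))),
    "positive")
})

test_that("nonlinear refit agrees with the log-linear estimate on clean data", {
  t <- seq(0, 40, length.out = 20)
  s <- list(times = t, values = 3 * exp(-0.08 * t))
  lin <- fit_exponential_rate(s, "decay")
  nl <- fit_exponential_rate(s, "decay", nonlinear = TRUE)
  expect_equal(nl$rate, lin$rate, tolerance = 1e-6)
})

test_that("estimated rates are recovered from noisy synthetic series within 2 SE", {
  for (true_rate in c(0.08, 0.46)) {
    hits <- 0L
    for (seed in 1:10) {
      series <- gen_marker_series(true_rate, "decay", sigma = 0.05, n = 20,
                                  seed = seed)
      f <- fit_exponential_rate(series, "decay")
      if (abs(f$rate - true_rate) <= 2 * f$se) hits <- hits + 1L
    }
    expect_gte(hits, 8L) # ~95% nominal; allow binomial wiggle
  }
})

test_that("42-week symmetric self-renewal interval converts to 0.0034 per day", {
  expect_equal(report_rate(rate_from_period_weeks(42)), 0.0034)
})

test_that("interconversion is far faster than the dedifferentiation benchmark", {
  # 0.08/day exceeds the stored benchmark by more than an order of magnitude
  expect_gt(0.08 / ips_dedifferentiation_rate, 10)
  expect_gt(0.02 / ips_dedifferentiation_rate, 5)
})

test_that("simulating the estimated rates reproduces the input equilibrium", {
  # close the loop: estimate rates from the equilibrium, simulate the
  # two-state chain at those rates, recover the occupancy
  eq <- equilibrium_distribution(0.2)
  r <- complete_rates(eq, lambda_met = 0.08)
  net <- two_state_net(r$lambda_emt, r$lambda_met, n_cells = 150)
  ens <- simulate_ensemble(net, 300, leap_settings(rng_seed = 17), n = 40,
                           times = c(0, 150, 300))
  met_final <- ens$arr[, 3, "MET"]
  expect_within_3se(mean(met_final), 0.8 * 150,
                    sqrt(150 * 0.8 * 0.2 / 40))
})
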
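test_that("rre_derivative evaluates the mean drift", {
  fx <- fixture_networks(b = 2, delta = 1, death_rate = 1, x0 = 1000)
  expect_equal(unname(rre_derivative(fx$pure_death, c(A = 1000))), -1000)
  birth <- build_network(list(species("A", "cell", 10)),
                         list(reaction("b", "A", c("A", "A"), 3, "renewal")))
  expect_equal(unname(rre_derivative(birth, c(A = 10))), 30)
  # two-channel birth-death, b = 2, delta = 1, x = 100
  expect_equal(unname(rre_derivative(fx$birth_death, c(A = 100))),
               2 * 100 - 1 * 100)
})

test_that("rre_derivative annihilates conserved moieties", {
  net <- build_niche_model()
  w <- c(gp130 = 1, IL6_gp130 = 1)
  full <- stats::setNames(numeric(nrow(net$nu)), rownames(net$nu))
  full[names(w)] <- w
  for (seed in 1:5) {
    set.seed(seed)
    x <- initial_state(net) + sample(0:50, nrow(net$species), replace = TRUE)
    expect_equal(sum(full * rre_derivative(net, x)), 0, tolerance = 1e-9)
  }
})

test_that("propensity_time_derivative follows the chain rule", {
  # zero-order source: no dependence on state
  src <- build_network(list(species("A")),
                       list(reaction("s", character(0), "A", 5,
                                     "transcription")))
  expect_equal(propensity_time_derivative(src, c(A = 0), 1), 0)
  # pure death at rate 1, x = 1000: dr/dt = 1 * dx/dt = -1000
  fx <- fixture_networks()
  expect_equal(propensity_time_derivative(fx$pure_death, c(A = 1000), 1),
               -1000)
  # bimolecular hand evaluation: A+B->AB, a=0.01, x=(10,100), only channel
  ab <- build_network(
    list(species("A", "cell", 10), species("B", "cell", 100), species("AB")),
    list(reaction("bind", c("A", "B"), "AB", 0.01, "binding")))
  expect_equal(propensity_time_derivative(ab, c(A = 10, B = 100, AB = 0), 1),
               -11)
})

test_that("leap_mean is the clamped Taylor-anticipated Poisson mean", {
  # static propensities: reduces exactly to r * tau
  src <- build_network(list(species("A")),
                       list(reaction("s", character(0), "A", 5,
                                     "transcription")))
  expect_equal(leap_mean(src, c(A = 0), 1, 2), 10)
  # r = 1000, dr/dt = -1000, tau = 0.1 -> 1000*0.1 - 1000*0.005 = 95
  fx <- fixture_networks()
  expect_equal(leap_mean(fx$pure_death, c(A = 1000), 1, 0.1), 95)
  # absent reactant: 0 for any tau
  expect_equal(leap_mean(fx$pure_death, c(A = 0), 1, 10), 0)
  # clamped at zero when the anticipated decline would drive it negative
  expect_equal(leap_mean(fx$pure_death, c(A = 1000), 1, 10), 0)
})

test_that("select_tau bounds the anticipated relative propensity change", {
  # static propensities give tau = max_tau
  src <- build_network(list(species("A")),
                       list(reaction("s", character(0), "A", 5,
                                     "transcription")))
  expect_equal(select_tau(src, c(A = 0), leap_settings(max_tau = 3)), 3)
  # birth-death b=0.5, delta=1, x=100: death r=100, dr/dt=-50;
  # criterion gives tau = 0.03 * 100 / 50 = 0.06
  bd <- fixture_networks(b = 0.5, delta = 1)$birth_death
  expect_equal(select_tau(bd, c(A = 100), leap_settings(epsilon = 0.03)),
               0.06)
  # reversible pair at equilibrium: net drift 0, tau = max_tau
  # stationary occupancy EMT:MET = lambda_emt : lambda_met = 1:4
  ts <- two_state_net(0.02, 0.08, 1)
  expect_equal(select_tau(ts, c(EMT = 2, MET = 8),
                          leap_settings(max_tau = 5)), 5)
  expect_error(select_tau(fixture_networks()$pure_death, c(A = 0)),
               "absorbing")
})

test_that("sal_step advances an absorbing state without changing it", {
  fx <- fixture_networks()
  st <- system_state(0, c(A = 0))
  out <- sal_step(fx$pure_death, st, leap_settings(max_tau = 2))
  expect_equal(out$time, 2)
  expect_equal(unname(out$counts), 0)
})

test_that("seeded runs are bit-reproducible", {
  net <- build_niche_model()
  s <- leap_settings(rng_seed = 123)
  t1 <- simulate_network(net, 50, s)
  t2 <- simulate_network(net, 50, s)
  expect_identical(t1$counts, t2$counts)
  e1 <- simulate_ensemble(net, 20, s, n = 3)
  e2 <- simulate_ensemble(net, 20, s, n = 3)
  expect_identical(e1$arr, e2$arr)
  # replicate seeds are derived by a counter: replicate 2 of an n=3 run
  # matches replicate 2 of an n=2 run
  e3 <- simulate_ensemble(net, 20, s, n = 2)
  expect_identical(e1$arr[2, , ], e3$arr[2, , ])
})

test_that("SAL ensemble mean of the linear death process matches 1000 e^-1", {
  fx <- fixture_networks()
  ens <- simulate_ensemble(fx$pure_death, 1, leap_settings(rng_seed = 9),
                           n = 1000, times = c(0, 1))
  final <- ens$arr[, 2, "A"]
  expect_within_3se(mean(final), 1000 * exp(-1), se_mean(final))
})

test_that("no trajectory ever contains a negative count", {
  fx <- fixture_networks()
  for (nm in names(fx)) {
    ens <- simulate_ensemble(fx[[nm]], 2, leap_settings(rng_seed = 4),
                             n = 50, times = seq(0, 2, by = 0.25))
    expect_gte(min(ens$arr), 0)
  }
  ens <- simulate_ensemble(build_niche_model(), 100,
                           leap_settings(rng_seed = 4), n = 5)
  expect_gte(min(ens$arr), 0)
})

test_that("exact SSA: pure death from 3 particles absorbs at zero", {
  net <- build_network(list(species("A", "cell", 3)),
                       list(reaction("d", "A", character(0), 1, "death")))
  tr <- ssa_exact(net, 50, seed = 2, times = seq(0, 50, by = 1))
  expect_equal(unname(tr$counts[nrow(tr$counts), 1]), 0)
  expect_true(all(diff(tr$counts[, 1]) <= 0))
})

test_that("subcritical birth-death goes extinct with probability ~1", {
  net <- fixture_networks(b = 1, delta = 2, x0 = 1)$birth_death
  ens <- simulate_ensemble(net, 30, leap_settings(rng_seed = 6), n = 200,
                           times = c(0, 30), method = "exact")
  expect_gte(mean(ens$arr[, 2, "A"] == 0), 0.95)
})

test_that("two-state occupancy matches detailed balance in the long run", {
  # 200 independent particles; expected MET occupancy 0.8
  ts <- two_state_net(0.02, 0.08, n_cells = 200)
  ens <- simulate_ensemble(ts, 400, leap_settings(rng_seed = 10), n = 40,
                           times = c(0, 200, 400))
  final <- ens$arr[, 3, "MET"]
  expect_within_3se(mean(final), 0.8 * 200,
                    sqrt(200 * 0.8 * 0.2 / 40))
})

test_that("ensemble mean lies between replicate extremes; tidy export works", {
  fx <- fixture_networks()
  ens <- simulate_ensemble(fx$birth_death, 1, leap_settings(rng_seed = 2),
                           n = 10, times = c(0, 0.5, 1))
  for (ti in 1:3) {
    expect_gte(ens$mean[ti, "A"], min(ens$arr[, ti, "A"]))
    expect_lte(ens$mean[ti, "A"], max(ens$arr[, ti, "A"]))
  }
  df <- ensemble_to_df(ens)
  expect_equal(nrow(df), 3)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(ens, path)
  out <- utils::read.csv(path)
  expect_equal(nrow(out), 3 * 10)
  expect_setequal(names(out), c("time", "species", "count", "replicate"))
})

test_that("the deterministic RRE trajectory matches the analytic decay", {
  fx <- fixture_networks()
  tr <- rre_trajectory(fx$pure_death, 2, times = c(0, 1, 2))
  expect_equal(unname(tr$counts[, "A"]), 1000 * exp(-c(0, 1, 2)),
               tolerance = 1e-5)
})
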
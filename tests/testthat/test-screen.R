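test_that("an empty target set leaves the network untouched", {
  net <- build_niche_model()
  net2 <- apply_inhibition(net, list())
  expect_identical(net2$rates, net$rates)
  expect_identical(net2$nu, net$nu)
})

test_that("inhibition scales exactly the targeted channels by exactly the factor", {
  net <- build_niche_model()
  inh <- apply_inhibition(net, "IL6")
  changed <- names(net$rates)[inh$rates != net$rates]
  expect_setequal(changed, niche_inhibition_map()$IL6)
  for (lab in changed) {
    expect_equal(inh$rates[[lab]] / net$rates[[lab]], 1e-10)
  }
  # propensity at equal state scales identically (binding channel)
  x <- initial_state(net)
  expect_equal(propensity(inh, x, "IL6_gp130_binding"),
               1e-10 * propensity(net, x, "IL6_gp130_binding"))
  # initial counts untouched
  expect_identical(initial_state(inh), x)
})

test_that("two targets scale their disjoint channel sets independently", {
  net <- build_niche_model()
  both <- apply_inhibition(net, c("HER2", "IL6"))
  map <- niche_inhibition_map()
  for (lab in map$HER2) expect_equal(both$rates[[lab]] / net$rates[[lab]], 1e-10)
  for (lab in map$IL6) expect_equal(both$rates[[lab]] / net$rates[[lab]], 1e-10)
  untouched <- setdiff(names(net$rates), c(map$HER2, map$IL6))
  expect_identical(both$rates[untouched], net$rates[untouched])
  expect_error(apply_inhibition(net, "NotATarget"), "unknown")
})

test_that("pairwise screens enumerate k(k-1)/2 conditions plus baseline", {
  net <- build_niche_model()
  for (k in c(3, 5)) {
    targets <- default_inhibition_targets()[seq_len(k)]
    res <- run_screen(net, targets, mode = "pairwise", horizon_days = 1,
                      reps = 1, times = c(0, 1),
                      settings = leap_settings(rng_seed = 1))
    expect_equal(nrow(res$conditions), k * (k - 1) / 2 + 1)
  }
  res1 <- run_screen(net, default_inhibition_targets()[1:4], mode = "single",
                     horizon_days = 1, reps = 1, times = c(0, 1),
                     settings = leap_settings(rng_seed = 1))
  expect_equal(nrow(res1$conditions), 5) # 4 singles + baseline
})

test_that("the baseline condition reproduces the plain ensemble bit for bit", {
  net <- build_niche_model()
  s <- leap_settings(rng_seed = 77)
  res <- run_screen(net, default_inhibition_targets()[1:2], mode = "single",
                    horizon_days = 50, reps = 3, settings = s)
  ens <- simulate_ensemble(net, 50, s, n = 3, times = res$times)
  expect_identical(res$cells$baseline$emt, ens$arr[, , "EMT"])
  expect_identical(res$cells$baseline$met, ens$arr[, , "MET"])
})

test_that("extinction frequency behaves like a first-passage probability", {
  # immortal pure birth: never extinct
  birth <- build_network(
    list(species("EMT", "cell", 0), species("MET", "cell", 5)),
    list(reaction("b", "MET", c("MET", "MET"), 0.5, "renewal"),
         reaction("t", "MET", "EMT", 0.01, "transition")))
  fake_targets <- list(inhibition_target("B", "b", 0.5))
  res <- run_screen(birth, fake_targets, mode = "single", horizon_days = 10,
                    reps = 30, settings = leap_settings(rng_seed = 3))
  expect_equal(extinction_frequency(res, "total", condition = "baseline"), 0)
  # independent exponential deaths: 5 particles at rate 1 by day 10
  death <- build_network(
    list(species("EMT", "cell", 0), species("MET", "cell", 5)),
    list(reaction("d", "MET", character(0), 1, "death")))
  resd <- run_screen(death, fake_targets <- list(inhibition_target("D", "d", 1)),
                     mode = "single", horizon_days = 10, reps = 200,
                     settings = leap_settings(rng_seed = 5))
  p_expected <- (1 - exp(-10))^5
  f <- extinction_frequency(resd, "MET", condition = "baseline")
  expect_lt(abs(f - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / 200) + 0.01)
  # monotone in time
  f500 <- extinction_frequency(resd, "MET", at_day = 5, condition = "baseline")
  expect_gte(f, f500)
})

test_that("ranking is deterministic under ties and respects dominance", {
  mk_cells <- function(mat) {
    list(times = c(0, 1), n = nrow(mat), emt = mat * 0, met = mat,
         total = mat, emt_mean = colMeans(mat * 0), met_mean = colMeans(mat),
         total_mean = colMeans(mat))
  }
  alive <- matrix(5, nrow = 4, ncol = 2)
  dead <- cbind(rep(3, 4), rep(0, 4))
  res <- structure(list(
    cells = list(baseline = mk_cells(alive), Zeta = mk_cells(alive),
                 Alpha = mk_cells(alive), Killer = mk_cells(dead)),
    horizon_days = 1, reps = 4, mode = "single", times = c(0, 1)),
    class = "screen_result")
  res$conditions <- data.frame(
    condition = c("baseline", "Zeta", "Alpha", "Killer"),
    extinction_emt = 0, extinction_met = c(0, 0, 0, 1),
    extinction_total = c(0, 0, 0, 1),
    mean_total_at_horizon = c(5, 5, 5, 0), stringsAsFactors = FALSE)
  ranked <- rank_combinations(res)
  # a condition with strictly dominated trajectories never outranks its
  # dominator; ties broken lexicographically
  expect_equal(ranked$condition, c("Killer", "Alpha", "Zeta"))
  expect_false("baseline" %in% ranked$condition)
})

test_that("a single-value sensitivity sweep is a plain ensemble", {
  net <- build_niche_model()
  s <- leap_settings(rng_seed = 12)
  sw <- sensitivity_sweep(net, "met_death", values = 0.02,
                          condition = "baseline", reps = 3,
                          horizon_days = 30, settings = s)
  ens <- simulate_ensemble(net, 30, s, n = 3, times = sw$sweeps[[1]]$times)
  expect_identical(sw$sweeps[[1]]$met, ens$arr[, , "MET"])
  expect_length(sweep_total_at_horizon(sw), 1)
})

test_that("stronger quiescence drive slows BCSC growth (asymmetric vs symmetric rates)", {
  # symmetric transition constants vs mesenchymal-biased constants
  sym <- build_niche_model(rates = c(
    EMT_by_IL6_gp130 = 1e-4, EMT_by_TGFb = 1e-4,
    MET_by_mir93 = 1e-4, MET_by_BMP = 1e-4, MET_by_HER2_EGFR = 1e-4))
  biased <- build_niche_model(rates = c(
    EMT_by_IL6_gp130 = 2.25e-4, EMT_by_TGFb = 2.25e-4,
    MET_by_mir93 = 1e-4, MET_by_BMP = 1e-4, MET_by_HER2_EGFR = 1e-4))
  s <- leap_settings(rng_seed = 14)
  e_sym <- simulate_ensemble(sym, 400, s, n = 12, times = c(0, 200, 400))
  e_bia <- simulate_ensemble(biased, 400, s, n = 12, times = c(0, 200, 400))
  tot_sym <- e_sym$arr[, 3, "EMT"] + e_sym$arr[, 3, "MET"]
  tot_bia <- e_bia$arr[, 3, "EMT"] + e_bia$arr[, 3, "MET"]
  expect_gt(mean(tot_sym), mean(tot_bia))
})
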
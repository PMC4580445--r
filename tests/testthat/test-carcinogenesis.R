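test_that("schedule_rates satisfies its defining equations exactly", {
  sch <- default_division_schedule()
  # healthy baseline: f = 0.2, ratio 1 -> beta = rho = 0.003375 (~0.0034)
  br <- schedule_rates(division_schedule(
    data.frame(start_day = 0, end_day = 365, f = 0.2, ratio = 1)),
    alpha = 0.027, day = 100)
  expect_equal(unname(br["beta"]), 0.003375)
  expect_equal(unname(br["rho"]), 0.003375)
  expect_equal(report_rate(br[["beta"]]), 0.0034)
  # year 1 of the default schedule: f = 0.2, ratio 5
  br1 <- schedule_rates(sch, 0.027, day = 10)
  expect_equal(unname(br1["beta"]), 0.005625)
  expect_equal(unname(br1["rho"]), 0.001125)
  # years 7+: f = 0.8, ratio 1 -> beta = rho = 0.054
  br7 <- schedule_rates(sch, 0.027, day = 365 * 7 + 1)
  expect_equal(unname(br7["beta"]), 0.054)
  # defining equations hold at every queried day
  for (day in c(0, 100, 400, 1000, 2000, 3000, 4379)) {
    br <- schedule_rates(sch, 0.027, day)
    i <- findInterval(day, sch$start_day)
    f <- sch$f[i]; ratio <- sch$ratio[i]
    expect_equal(sum(br) / (0.027 + sum(br)), f, tolerance = 1e-12)
    expect_equal(br[["beta"]] / br[["rho"]], ratio, tolerance = 1e-12)
  }
  expect_error(schedule_rates(sch, 0.027, day = 1e5), "outside")
})

test_that("schedule validation rejects gaps and bad fractions", {
  expect_error(division_schedule(data.frame(
    start_day = c(0, 400), end_day = c(365, 800), f = 0.5, ratio = 1)))
  expect_error(division_schedule(data.frame(
    start_day = 0, end_day = 365, f = 1.2, ratio = 1)))
})

test_that("the growth model has the documented structure", {
  m <- build_growth_model()
  expect_equal(sum(initial_state(m$network)), 625)
  labels <- names(m$network$rates)
  # quiescent mesenchymal cells: no division or death channels
  emt_consuming <- vapply(seq_along(labels), function(j) {
    m$network$nu["EMT", j] < 0
  }, logical(1))
  expect_equal(labels[emt_consuming], "met_transition")
  # schedule carries per-period beta/rho; year-5 onward beta = rho
  expect_equal(nrow(m$schedule), 12)
  expect_equal(m$schedule$beta[5:12], m$schedule$rho[5:12])
  expect_equal(m$schedule$beta[1:4], 5 * m$schedule$rho[1:4])
})

test_that("beta = rho with constant f keeps the expected BCSC pool flat", {
  sch <- division_schedule(
    data.frame(start_day = 0, end_day = 2000, f = 0.2, ratio = 1))
  m <- build_growth_model(schedule = sch)
  tr <- rre_growth(m, times = seq(0, 2000, by = 100))
  bcsc <- tr$counts[, "EMT"] + tr$counts[, "MET"]
  expect_equal(unname(bcsc[length(bcsc)]), unname(bcsc[1]), tolerance = 1e-6)
})

test_that("the mean trajectory is non-decreasing when all death rates are zero", {
  p <- hierarchy_params(tc_death = 0, bcsc_death = 0)
  m <- build_growth_model(p)
  tr <- rre_growth(m, times = seq(0, 4380, by = 60))
  expect_true(all(diff(tr$totals) > -1e-6))
})

test_that("12-year default run shows decelerating growth toward ~1e9 cells", {
  m <- build_growth_model()
  ens <- simulate_growth(m, reps = 8, settings = leap_settings(rng_seed = 21,
                                                              max_tau = 2))
  final <- ens$mean_total[length(ens$mean_total)]
  expect_gt(final, 5e8)
  expect_lt(final, 3e9)
  # continuous deceleration: specific growth rate of the mean trajectory
  # falls over the last two-thirds of the run
  lt <- diff(log(ens$mean_total))
  n <- length(lt)
  expect_lt(mean(lt[(2 * n %/% 3):n]), mean(lt[(n %/% 3):(2 * n %/% 3)]))
  expect_gte(min(ens$arr), 0)
})

test_that("without a division shift there is no Gompertzian expansion", {
  sch <- division_schedule(
    data.frame(start_day = 0, end_day = 4380, f = 0.2, ratio = 1))
  m <- build_growth_model(schedule = sch)
  tr <- rre_growth(m)
  expect_lt(tr$totals[length(tr$totals)], 1e5) # vs ~1.3e9 with the shift
  # beta <= rho throughout: no appreciable stem-compartment expansion
  sch2 <- division_schedule(
    data.frame(start_day = 0, end_day = 4380, f = 0.5, ratio = 1))
  tr2 <- rre_growth(build_growth_model(schedule = sch2))
  bcsc2 <- tr2$counts[, "EMT"] + tr2$counts[, "MET"]
  expect_lt(max(bcsc2) / bcsc2[1], 1.01)
})

test_that("a larger peak beta-rho gap raises the asymptotic population", {
  totals <- vapply(c(4.5, 5.5), function(ratio) {
    sch <- default_division_schedule()
    sch$ratio[1:4] <- ratio
    m <- build_growth_model(schedule = division_schedule(as.data.frame(sch)))
    ens <- simulate_growth(m, reps = 6,
                           settings = leap_settings(rng_seed = 8, max_tau = 2))
    ens$mean_total[length(ens$mean_total)]
  }, numeric(1))
  expect_gt(totals[2], totals[1])
})

test_that("delaying the beta > rho window shifts growth later and higher", {
  early <- default_division_schedule()
  late <- early
  late$ratio <- c(rep(1, 2), rep(5, 4), rep(1, 6))
  m_early <- build_growth_model(schedule = division_schedule(as.data.frame(early)))
  m_late <- build_growth_model(schedule = division_schedule(as.data.frame(late)))
  tr_e <- rre_growth(m_early)
  tr_l <- rre_growth(m_late)
  half_time <- function(tr) tr$times[min(which(tr$totals >= max(tr$totals) / 2))]
  expect_gt(half_time(tr_l), half_time(tr_e))
  expect_gt(tr_l$totals[length(tr_l$totals)],
            tr_e$totals[length(tr_e$totals)])
})

test_that("the calibration grid search ranks the shipped defaults first", {
  res <- calibrate_progenitor_rates(
    bpp_division = c(0.02),
    bpp_differentiation = c(0.05, 0.06),
    tc_death = c(7.5e-4, 8.5e-4))
  p <- hierarchy_params()
  expect_equal(res$bpp_differentiation[1], p$bpp_differentiation)
  expect_equal(res$tc_death[1], p$tc_death)
})
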
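# Carcinogenesis hierarchy: BCSC (EMT-like quiescent / MET-like
# proliferative) -> bipotent progenitor (BPP) -> differentiated luminal or
# basal cells (TC). Only MET-like BCSCs divide: symmetric self-renewal
# (beta, -> 2 MET), asymmetric self-renewal (alpha, -> MET + BPP), symmetric
# differentiation (rho, -> 2 BPP). The symmetric-division fraction
# f = (beta + rho) / (alpha + beta + rho) rises yearly during
# carcinogenesis; progenitor and differentiated-cell rates stay constant.

#' Hierarchy rate parameters
#'
#' `alpha`, `beta`, `rho` are the asymmetric self-renewal, symmetric
#' self-renewal, and symmetric differentiation rates of epithelial BCSCs
#' (cell^-1 day^-1); when a [division_schedule()] is supplied, `beta` and
#' `rho` are recomputed per period from the schedule and these fields serve
#' as the no-schedule baseline. `lambda_emt`/`lambda_met` are the
#' niche-independent state-transition rates. Progenitor and
#' differentiated-cell rates are not published; the defaults here were
#' calibrated against the Gompertz description of breast tumor growth
#' (procedure in the methods vignette) and shipped frozen.
#'
#' @param alpha Asymmetric self-renewal rate (default 0.027).
#' @param beta Symmetric self-renewal rate (healthy baseline 0.0034).
#' @param rho Symmetric differentiation rate (healthy baseline 0.0034).
#' @param lambda_emt,lambda_met BCSC state-transition rates (0.02, 0.08).
#' @param bcsc_death Death rate of epithelial BCSCs (default 0 during
#'   carcinogenesis runs).
#' @param bpp_division BPP symmetric division rate (day^-1).
#' @param bpp_differentiation Total BPP differentiation rate (day^-1),
#'   split evenly between luminal and basal fates.
#' @param tc_death Differentiated-cell death rate (day^-1).
#' @return A `"hierarchy_params"` object.
#' @export
hierarchy_params <- function(alpha = 0.027, beta = 0.0034, rho = 0.0034,
                             lambda_emt = 0.02, lambda_met = 0.08,
                             bcsc_death = 0,
                             bpp_division = 0.02,
                             bpp_differentiation = 0.06,
                             tc_death = 8.5e-4) {
  p <- list(alpha = alpha, beta = beta, rho = rho,
            lambda_emt = lambda_emt, lambda_met = lambda_met,
            bcsc_death = bcsc_death, bpp_division = bpp_division,
            bpp_differentiation = bpp_differentiation, tc_death = tc_death)
  stopifnot(all(unlist(p) >= 0))
  structure(p, class = "hierarchy_params")
}

#' Yearly symmetric-division schedule
#'
#' @param periods Data frame with columns `start_day`, `end_day`,
#'   `f` (symmetric-division fraction, in (0, 1)), and `ratio`
#'   (beta-to-rho ratio, > 0). Periods must be contiguous and
#'   non-overlapping.
#' @return A `"division_schedule"` object.
#' @export
division_schedule <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("start_day", "end_day", "f", "ratio") %in% names(periods)))
  stopifnot(all(periods$end_day > periods$start_day),
            all(periods$f > 0), all(periods$f < 1), all(periods$ratio > 0))
  if (nrow(periods) > 1L) {
    stopifnot(all(abs(periods$start_day[-1L] -
                        periods$end_day[-nrow(periods)]) < 1e-9))
  }
  structure(periods, class = c("division_schedule", "data.frame"))
}

#' The default 12-year carcinogenesis schedule
#'
#' Symmetric-division fraction stepped yearly: 20% in year 1, 30% in year 2,
#' ..., 70% in year 6, 80% in years 7-12; symmetric self-renewal exceeds
#' symmetric differentiation five-fold during years 1-4 (`beta = 5 rho`) and
#' equals it afterwards. One year = 365 days, switches exactly at day 365 k.
#'
#' @param years Total span (default 12).
#' @return A [division_schedule()].
#' @export
default_division_schedule <- function(years = 12) {
  f <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, rep(0.8, max(years - 6, 0)))[seq_len(years)]
  ratio <- c(rep(5, 4), rep(1, max(years - 4, 0)))[seq_len(years)]
  division_schedule(data.frame(
    start_day = 365 * (seq_len(years) - 1),
    end_day = 365 * seq_len(years),
    f = f, ratio = ratio))
}

#' Symmetric self-renewal and differentiation rates on a given day
#'
#' Solves `(beta + rho) / (alpha + beta + rho) = f(day)` and
#' `beta / rho = ratio(day)` for the scheduled period containing `day`.
#'
#' @param schedule A [division_schedule()].
#' @param alpha Asymmetric self-renewal rate held constant.
#' @param day Day since transformation.
#' @return Named vector `c(beta = , rho = )` (cell^-1 day^-1).
#' @examples
#' # f = 0.2, ratio 1 recovers the healthy baseline ~0.0034
#' schedule_rates(default_division_schedule(), alpha = 0.027, day = 365 * 5)
#' @export
schedule_rates <- function(schedule, alpha, day) {
  i <- which(schedule$start_day <= day & day < schedule$end_day)
  if (!length(i) && abs(day - schedule$end_day[nrow(schedule)]) < 1e-9) {
    i <- nrow(schedule)
  }
  if (!length(i)) stop("day ", day, " outside the schedule", call. = FALSE)
  f <- schedule$f[i[1L]]
  ratio <- schedule$ratio[i[1L]]
  tot <- alpha * f / (1 - f)
  c(beta = tot * ratio / (1 + ratio), rho = tot / (1 + ratio))
}

#' Default initial cell populations
#'
#' 25 BCSCs (5 quiescent mesenchymal, 20 proliferating epithelial), 100
#' bipotent progenitors, and 500 differentiated cells (split evenly between
#' luminal and basal).
#'
#' @return Named numeric vector of counts.
#' @export
default_cell_populations <- function() {
  c(EMT = 5, MET = 20, BPP = 100, TC_luminal = 250, TC_basal = 250)
}

.hierarchy_network <- function(params, beta, rho, init) {
  build_network(
    list(species("EMT", "cell", init[["EMT"]]),
         species("MET", "cell", init[["MET"]]),
         species("BPP", "cell", init[["BPP"]]),
         species("TC_luminal", "cell", init[["TC_luminal"]]),
         species("TC_basal", "cell", init[["TC_basal"]])),
    list(
      reaction("symmetric_renewal", "MET", c("MET", "MET"), beta, "renewal"),
      reaction("asymmetric_renewal", "MET", c("MET", "BPP"), params$alpha,
               "renewal"),
      reaction("symmetric_differentiation", "MET", c("BPP", "BPP"), rho,
               "renewal"),
      reaction("bcsc_death", "MET", character(0), params$bcsc_death, "death"),
      reaction("emt_transition", "MET", "EMT", params$lambda_emt,
               "transition"),
      reaction("met_transition", "EMT", "MET", params$lambda_met,
               "transition"),
      reaction("bpp_division", "BPP", c("BPP", "BPP"), params$bpp_division,
               "renewal"),
      reaction("bpp_diff_luminal", "BPP", "TC_luminal",
               params$bpp_differentiation / 2, "transition"),
      reaction("bpp_diff_basal", "BPP", "TC_basal",
               params$bpp_differentiation / 2, "transition"),
      reaction("tc_luminal_death", "TC_luminal", character(0),
               params$tc_death, "death"),
      reaction("tc_basal_death", "TC_basal", character(0), params$tc_death,
               "death")))
}

#' Build the time-inhomogeneous carcinogenesis growth model
#'
#' The hierarchy network plus the per-period `(beta, rho)` values implied by
#' the division schedule. Quiescent mesenchymal BCSCs carry no division or
#' death channels; their only channels are the state transitions.
#'
#' @param params A [hierarchy_params()] object.
#' @param schedule A [division_schedule()] (default
#'   [default_division_schedule()]).
#' @param init Initial populations (default [default_cell_populations()]).
#' @return A `"growth_model"`: the base `network`, the `schedule` with
#'   per-period beta/rho columns, `params`, `init`.
#' @export
build_growth_model <- function(params = hierarchy_params(),
                               schedule = default_division_schedule(),
                               init = default_cell_populations()) {
  stopifnot(inherits(params, "hierarchy_params"))
  br <- t(vapply(seq_len(nrow(schedule)), function(i) {
    schedule_rates(schedule, params$alpha, schedule$start_day[i])
  }, numeric(2)))
  sched <- as.data.frame(schedule)
  sched$beta <- br[, "beta"]
  sched$rho <- br[, "rho"]
  net <- .hierarchy_network(params, sched$beta[1L], sched$rho[1L], init)
  structure(list(network = net, schedule = sched, params = params,
                 init = init), class = "growth_model")
}

.segment_run <- function(model, x, seg, times, settings, deterministic) {
  net <- set_rates(model$network,
                   c(symmetric_renewal = seg$beta,
                     symmetric_differentiation = seg$rho))
  seg_times <- times[times >= seg$start_day - 1e-9 &
                       times < seg$end_day - 1e-9]
  rec <- c(seg_times, seg$end_day)
  if (deterministic) {
    f <- function(t, y, parms) {
      list(as.numeric(net$nu %*% propensities(net, pmax(y, 0))))
    }
    sol <- deSolve::ode(y = x, times = unique(c(seg$start_day, rec)),
                        func = f, parms = NULL, method = "lsoda")
    m <- sol[match(rec, sol[, 1L]), -1L, drop = FALSE]
  } else {
    m <- .run_cpp(net, x, seg$start_day, seg$end_day, rec, settings,
                  exact = FALSE)
  }
  list(recorded = m[seq_along(seg_times), , drop = FALSE],
       carry = as.numeric(m[nrow(m), ]))
}

.growth_path <- function(model, times, settings, deterministic = FALSE) {
  x <- as.numeric(initial_state(model$network))
  out <- matrix(NA_real_, nrow = length(times),
                ncol = nrow(model$network$species))
  filled <- 0L
  for (i in seq_len(nrow(model$schedule))) {
    seg <- model$schedule[i, ]
    res <- .segment_run(model, x, seg, times, settings, deterministic)
    k <- nrow(res$recorded)
    if (k) out[filled + seq_len(k), ] <- res$recorded
    filled <- filled + k
    x <- res$carry
  }
  if (filled < length(times)) out[length(times), ] <- x
  colnames(out) <- model$network$species$name
  out
}

#' Simulate carcinogenesis growth
#'
#' Runs the hierarchy model over the full schedule, switching `beta`/`rho`
#' exactly at period boundaries, for `reps` stochastic replicates (SAL
#' stepping), and summarizes per-compartment and total-cell trajectories.
#'
#' @param model A [build_growth_model()] object.
#' @param reps Number of replicates (>= 1).
#' @param settings A [leap_settings()]; its `rng_seed` is the ensemble root
#'   seed.
#' @param times Recording grid (default: every 30 days plus the endpoint).
#' @return A `"growth_ensemble"`: `times`, `species`, `n`, per-species
#'   `mean` matrix, replicate array `arr`, `totals` (replicate x time), and
#'   `mean_total`.
#' @export
simulate_growth <- function(model, reps = 20,
                            settings = leap_settings(max_tau = 2),
                            times = NULL) {
  t_final <- model$schedule$end_day[nrow(model$schedule)]
  if (is.null(times)) times <- unique(c(seq(0, t_final, by = 30), t_final))
  root <- if (is.null(settings$rng_seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    settings$rng_seed
  }
  d <- nrow(model$network$species)
  arr <- array(NA_real_, dim = c(reps, length(times), d),
               dimnames = list(NULL, NULL, model$network$species$name))
  seeds <- vapply(seq_len(reps), function(i) .derive_seed(root, i), integer(1))
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    arr[i, , ] <- .growth_path(model, times, settings)
  }
  totals <- apply(arr, c(1, 2), sum)
  structure(list(times = times, species = model$network$species$name,
                 n = reps, mean = apply(arr, c(2, 3), mean), arr = arr,
                 totals = totals, mean_total = colMeans(totals),
                 seeds = seeds),
            class = "growth_ensemble")
}

#' Deterministic mean-field growth trajectory
#'
#' Integrates the reaction rate equation of the hierarchy model piecewise
#' over the schedule. Fast, noise-free companion of [simulate_growth()],
#' used for calibrating the unpublished progenitor-compartment rates.
#'
#' @inheritParams simulate_growth
#' @return A `"trajectory"` plus a `total` column convention: list with
#'   `times`, `counts`, `totals`.
#' @export
rre_growth <- function(model, times = NULL) {
  t_final <- model$schedule$end_day[nrow(model$schedule)]
  if (is.null(times)) times <- unique(c(seq(0, t_final, by = 30), t_final))
  m <- .growth_path(model, times, leap_settings(), deterministic = TRUE)
  list(times = times, counts = m, totals = rowSums(m))
}

#' Calibrate progenitor-compartment rates against a Gompertz target
#'
#' Grid search over (`bpp_division`, `bpp_differentiation`, `tc_death`)
#' minimizing the squared log-distance between the deterministic 12-year
#' mean trajectory and a target Gompertz curve. This is the documented
#' procedure that produced the frozen defaults of [hierarchy_params()].
#'
#' @param target A [gompertz_params()] object (the published fit:
#'   `A0 = 0.0193`, `c = 0.00133`, `N0 = 625`).
#' @param bpp_division,bpp_differentiation,tc_death Candidate grids.
#' @param params,schedule,init Passed to [build_growth_model()].
#' @return Data frame of candidates with their loss, best first.
#' @export
calibrate_progenitor_rates <- function(
    target = gompertz_params(0.0193, 0.00133, 625),
    bpp_division = c(0.015, 0.02, 0.025),
    bpp_differentiation = c(0.05, 0.06, 0.07),
    tc_death = c(7.5e-4, 8e-4, 8.5e-4),
    params = hierarchy_params(), schedule = default_division_schedule(),
    init = default_cell_populations()) {
  grid <- expand.grid(bpp_division = bpp_division,
                      bpp_differentiation = bpp_differentiation,
                      tc_death = tc_death)
  grid$loss <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$bpp_division <- grid$bpp_division[i]
    p$bpp_differentiation <- grid$bpp_differentiation[i]
    p$tc_death <- grid$tc_death[i]
    model <- build_growth_model(p, schedule, init)
    tr <- rre_growth(model)
    tgt <- gompertz_value(target, tr$times)
    grid$loss[i] <- sum((tr$totals - tgt)^2)
  }
  grid[order(grid$loss), ]
}
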
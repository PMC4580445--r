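#' Leap control settings for stochastic simulation
#'
#' @param epsilon Dimensionless error-control parameter bounding the
#'   anticipated relative propensity change over one leap:
#'   `|dr_j/dt| * tau <= epsilon * max(r_j, a_j)`. Default 0.03.
#' @param ssa_threshold Particle count below which a channel consuming that
#'   species is treated as critical and fired one event at a time (exact
#'   stepping); `0` disables the hybrid and leaps every channel.
#' @param max_tau Upper bound on the leap length (days).
#' @param rng_seed Optional integer root seed; replicate seeds in ensembles
#'   are derived from it by a counter scheme so that replicate `i` is
#'   reproducible independently of how many replicates are run.
#' @return A `"leap_settings"` object.
#' @export
leap_settings <- function(epsilon = 0.03, ssa_threshold = 10, max_tau = 1,
                          rng_seed = NULL) {
  stopifnot(epsilon > 0, epsilon < 1, ssa_threshold >= 0, max_tau > 0)
  structure(list(epsilon = epsilon, ssa_threshold = ssa_threshold,
                 max_tau = max_tau, rng_seed = rng_seed),
            class = "leap_settings")
}

#' System state at a time point
#'
#' @param time Time in days.
#' @param counts Named non-negative integer vector of particle counts.
#' @return A `"system_state"` object.
#' @export
system_state <- function(time, counts) {
  stopifnot(time >= 0, all(counts >= 0))
  structure(list(time = time, counts = counts), class = "system_state")
}

.state_counts <- function(network, state) {
  x <- if (inherits(state, "system_state")) state$counts else state
  if (!is.null(names(x))) x <- x[network$species$name]
  stopifnot(length(x) == nrow(network$species), !anyNA(x))
  as.numeric(x)
}

#' Mean drift of the reaction rate equation
#'
#' Evaluates the right-hand side of the deterministic reaction rate equation
#' (RRE), `d mu/dt = sum_j r_j(x) nu^j`, at the current counts. This is the
#' drift that SAL uses to anticipate propensity change within a leap.
#'
#' @param network A reaction network.
#' @param state Counts vector or [system_state()].
#' @return Numeric length-`d` vector (particles day^-1), named by species.
#' @export
rre_derivative <- function(network, state) {
  x <- .state_counts(network, state)
  r <- propensities(network, x)
  stats::setNames(as.numeric(network$nu %*% r), network$species$name)
}

#' Anticipated time derivative of one channel's propensity
#'
#' Chain rule `dr_j/dt = sum_k (dr_j/dx_k) (dx_k/dt)` with `dx/dt` taken from
#' [rre_derivative()].
#'
#' @inheritParams rre_derivative
#' @param j Channel index or label.
#' @return Scalar rate of change of the propensity (day^-2).
#' @export
propensity_time_derivative <- function(network, state, j) {
  if (is.character(j)) j <- match(j, names(network$rates))
  x <- .state_counts(network, state)
  dx <- as.numeric(network$nu %*% propensities(network, x))
  a <- unname(network$rates[j])
  i1 <- network$reactant_index[1L, j]
  i2 <- network$reactant_index[2L, j]
  if (is.na(i1)) return(0)
  if (is.na(i2)) return(a * dx[i1])
  if (i1 == i2) return(a * (x[i1] - 0.5) * dx[i1])
  a * (x[i1] * dx[i2] + x[i2] * dx[i1])
}

#' Poisson mean of a channel over one leap
#'
#' The SAL leap mean `r_j(x) tau + 0.5 (dr_j/dt) tau^2`, clamped at zero when
#' the anticipated decline would drive it negative.
#'
#' @inheritParams propensity_time_derivative
#' @param tau Leap length in days.
#' @return Non-negative expected event count.
#' @export
leap_mean <- function(network, state, j, tau) {
  stopifnot(tau > 0)
  if (is.character(j)) j <- match(j, names(network$rates))
  x <- .state_counts(network, state)
  r <- propensities(network, x)[j]
  max(0, r * tau + 0.5 * propensity_time_derivative(network, x, j) * tau^2)
}

#' Select a leap length
#'
#' Largest `tau <= max_tau` such that every active channel's anticipated
#' relative propensity change satisfies
#' `|dr_j/dt| * tau <= epsilon * max(r_j, a_j)` and every leap mean stays
#' non-negative (`tau <= 2 r_j / |dr_j/dt|` for declining channels).
#'
#' @inheritParams rre_derivative
#' @param settings A [leap_settings()] object.
#' @return Leap length in days.
#' @export
select_tau <- function(network, state, settings = leap_settings()) {
  x <- .state_counts(network, state)
  r <- propensities(network, x)
  if (all(r == 0)) {
    stop("all propensities are zero: absorbing state", call. = FALSE)
  }
  a <- unname(network$rates)
  tau <- settings$max_tau
  for (j in which(r > 0)) {
    g <- abs(propensity_time_derivative(network, x, j))
    if (g > 0) {
      tau <- min(tau, settings$epsilon * max(r[j], a[j]) / g)
      if (propensity_time_derivative(network, x, j) < 0) {
        tau <- min(tau, 2 * r[j] / g)
      }
    }
  }
  tau
}

#' One SAL step (reference implementation)
#'
#' Draws Poisson event counts for every channel over a leap chosen by
#' [select_tau()] and applies the stoichiometric update. If any count would
#' go negative the leap is rejected and halved (bounded retries), then the
#' step falls back to a single exact-SSA event. With all propensities zero
#' the state is returned unchanged with time advanced by `max_tau`.
#'
#' This R implementation defines the stepping semantics and backs the unit
#' tests; production simulation goes through the compiled engine in
#' [simulate_network()], which adds critical-channel partitioning.
#'
#' @param network A reaction network.
#' @param state A [system_state()].
#' @param settings A [leap_settings()] object.
#' @return The new [system_state()].
#' @export
sal_step <- function(network, state, settings = leap_settings()) {
  stopifnot(inherits(state, "system_state"))
  x <- .state_counts(network, state)
  r <- propensities(network, x)
  if (all(r == 0)) {
    return(system_state(state$time + settings$max_tau,
                        stats::setNames(x, network$species$name)))
  }
  tau <- select_tau(network, x, settings)
  drdt <- vapply(seq_along(r), function(j) {
    propensity_time_derivative(network, x, j)
  }, numeric(1))
  for (try in seq_len(40L)) {
    w <- pmax(0, r * tau + 0.5 * drdt * tau^2)
    k <- stats::rpois(length(w), w)
    xn <- x + as.numeric(network$nu %*% k)
    if (all(xn >= 0)) {
      return(system_state(state$time + tau,
                          stats::setNames(xn, network$species$name)))
    }
    tau <- tau / 2
  }
  # fallback: one exact event
  tau <- stats::rexp(1, sum(r))
  j <- sample.int(length(r), 1L, prob = r)
  xn <- x + network$nu[, j]
  system_state(state$time + tau, stats::setNames(xn, network$species$name))
}

.rec_times <- function(t_final, times, t0 = 0) {
  if (is.null(times)) times <- seq(t0, t_final, length.out = 101L)
  stopifnot(!is.unsorted(times), times[1L] >= t0,
            times[length(times)] <= t_final + 1e-9)
  as.numeric(times)
}

.run_cpp <- function(network, x0, t0, t_final, times, settings, exact) {
  ridx <- network$reactant_index
  ridx[is.na(ridx)] <- 0L
  m <- cpp_simulate(network$nu * 1.0, unname(network$rates), ridx - 1L,
                    x0, t0, t_final, times,
                    settings$epsilon, settings$ssa_threshold,
                    settings$max_tau, exact)
  colnames(m) <- network$species$name
  m
}

#' Simulate a trajectory
#'
#' Hybrid SAL simulation of a network from its initial counts (or `init`)
#' to `t_final`, recorded on a time grid. Channels whose consumed species
#' fall below `ssa_threshold` fire exactly, one event at a time; the rest
#' are leaped with step-anticipated Poisson means.
#'
#' @param network A reaction network.
#' @param t_final End time (days).
#' @param settings A [leap_settings()] object; its `rng_seed` (if non-NULL)
#'   seeds the run.
#' @param times Recording grid (defaults to 101 evenly spaced points).
#' @param init Optional initial counts overriding the network's.
#' @param method `"sal"` (default hybrid) or `"exact"` (pure SSA).
#' @return A `"trajectory"`: list with `times` and a `counts` matrix
#'   (time points x species).
#' @export
simulate_network <- function(network, t_final, settings = leap_settings(),
                             times = NULL, init = NULL,
                             method = c("sal", "exact")) {
  method <- match.arg(method)
  stopifnot(t_final > 0)
  if (!is.null(settings$rng_seed)) set.seed(settings$rng_seed)
  x0 <- if (is.null(init)) initial_state(network) else .state_counts(network, init)
  times <- .rec_times(t_final, times)
  m <- .run_cpp(network, as.numeric(x0), 0, t_final, times, settings,
                exact = identical(method, "exact"))
  structure(list(times = times, counts = m), class = "trajectory")
}

#' Exact Gillespie simulation
#'
#' Direct-method SSA: exponential waiting time with the total propensity,
#' channel chosen proportionally to its propensity. Serves as the oracle for
#' validating the leaping engine.
#'
#' @inheritParams simulate_network
#' @param seed Optional integer seed.
#' @return A `"trajectory"` object.
#' @export
ssa_exact <- function(network, t_final, seed = NULL, times = NULL,
                      init = NULL) {
  settings <- leap_settings(rng_seed = seed)
  simulate_network(network, t_final, settings, times, init, method = "exact")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$times), " time points, ",
      ncol(x$counts), " species, t in [", x$times[1L], ", ",
      x$times[length(x$times)], "] days\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$counts)),
    species = rep(colnames(x$counts), each = length(x$times)),
    count = as.vector(x$counts),
    stringsAsFactors = FALSE)
}

.derive_seed <- function(root, i) {
  as.integer((as.numeric(root) + 1000003 * as.numeric(i)) %% 2147483629)
}

#' Simulate an ensemble of replicate trajectories
#'
#' Runs `n` independent replicates with per-replicate seeds derived from the
#' root seed by a counter scheme (replicate `i` always sees the same seed,
#' regardless of `n` or execution order).
#'
#' @inheritParams simulate_network
#' @param n Number of replicates.
#' @return An `"ensemble_summary"`: `times`, `species`, replicate count `n`,
#'   `mean` and `var` matrices (time x species), the full replicate array
#'   `arr` (replicate x time x species), and the `seeds` used.
#' @export
simulate_ensemble <- function(network, t_final, settings = leap_settings(),
                              n = 100, times = NULL, init = NULL,
                              method = c("sal", "exact")) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  root <- if (is.null(settings$rng_seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    settings$rng_seed
  }
  x0 <- if (is.null(init)) initial_state(network) else .state_counts(network, init)
  times <- .rec_times(t_final, times)
  arr <- array(NA_real_, dim = c(n, length(times), nrow(network$species)),
               dimnames = list(NULL, NULL, network$species$name))
  seeds <- vapply(seq_len(n), function(i) .derive_seed(root, i), integer(1))
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    arr[i, , ] <- .run_cpp(network, as.numeric(x0), 0, t_final, times,
                           settings, exact = identical(method, "exact"))
  }
  structure(list(
    times = times, species = network$species$name, n = n,
    mean = apply(arr, c(2, 3), mean),
    var = apply(arr, c(2, 3), stats::var),
    arr = arr, seeds = seeds
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary: ", x$n, " replicates, ", length(x$times),
      " time points, ", length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Per-species ensemble mean at given times
#'
#' @param ensemble An `"ensemble_summary"`.
#' @param species Species name(s); default all.
#' @param at_time Time point (must lie on the recording grid); default the
#'   final grid time.
#' @return Named numeric vector of means.
#' @export
ensemble_mean_at <- function(ensemble, species = NULL, at_time = NULL) {
  if (is.null(at_time)) at_time <- ensemble$times[length(ensemble$times)]
  ti <- which.min(abs(ensemble$times - at_time))
  if (abs(ensemble$times[ti] - at_time) > 1e-6) {
    stop("at_time is not on the recording grid", call. = FALSE)
  }
  m <- ensemble$mean[ti, ]
  names(m) <- ensemble$species
  if (!is.null(species)) m <- m[species]
  m
}

#' Tidy data frame of an ensemble's mean trajectories
#'
#' @param ensemble An `"ensemble_summary"`.
#' @return Data frame with columns time, species, mean, var.
#' @export
ensemble_to_df <- function(ensemble) {
  data.frame(
    time = rep(ensemble$times, times = length(ensemble$species)),
    species = rep(ensemble$species, each = length(ensemble$times)),
    mean = as.vector(ensemble$mean),
    var = as.vector(ensemble$var),
    stringsAsFactors = FALSE)
}

#' Deterministic mean-field trajectory (reaction rate equation)
#'
#' Integrates the RRE `d mu/dt = sum_j r_j(mu) nu^j` with `deSolve`. This is
#' the non-stochastic companion of [simulate_network()], used for fast
#' parameter calibration; it ignores demographic noise entirely.
#'
#' @inheritParams simulate_network
#' @return A `"trajectory"` object (fractional mean counts).
#' @export
rre_trajectory <- function(network, t_final, times = NULL, init = NULL) {
  x0 <- if (is.null(init)) initial_state(network) else .state_counts(network, init)
  times <- .rec_times(t_final, times)
  f <- function(t, y, parms) list(as.numeric(network$nu %*% propensities(network, pmax(y, 0))))
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = f,
                      parms = NULL, method = "lsoda")
  m <- sol[, -1L, drop = FALSE]
  colnames(m) <- network$species$name
  structure(list(times = times, counts = m), class = "trajectory")
}

#' Write trajectories to a tidy CSV
#'
#' One row per (time, species, count, replicate); a single trajectory gets
#' replicate 1.
#'
#' @param x A `"trajectory"` or `"ensemble_summary"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- if (inherits(x, "trajectory")) {
    cbind(as.data.frame(x), replicate = 1L)
  } else {
    do.call(rbind, lapply(seq_len(x$n), function(i) {
      data.frame(time = rep(x$times, times = length(x$species)),
                 species = rep(x$species, each = length(x$times)),
                 count = as.vector(x$arr[i, , ]),
                 replicate = i, stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
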
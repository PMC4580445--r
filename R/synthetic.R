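# Synthetic inputs emulating the unpublished experimental series the
# estimators are designed for: exponentially decaying/rising marker
# expression with multiplicative log-normal noise, two-state occupancy data
# with known equilibrium, and noisy Gompertz growth observations. Every
# generator is a pure function of its spec (same spec => identical data).

#' Specification of a synthetic dataset
#'
#' Serialized alongside every generated dataset so it can be regenerated
#' bit-for-bit.
#'
#' @param generator Generator name.
#' @param params Named list of true parameters.
#' @param sigma Multiplicative log-normal noise (sd of log values), >= 0.
#' @param n Number of points/replicates, >= 1.
#' @param seed Integer seed.
#' @return A `"synthetic_spec"` object.
#' @export
synthetic_spec <- function(generator, params, sigma, n, seed) {
  stopifnot(sigma >= 0, n >= 1)
  structure(list(generator = generator, params = params, sigma = sigma,
                 n = n, seed = seed), class = "synthetic_spec")
}

#' Generate an exponential marker-expression time course
#'
#' Emulates vimentin mRNA expression after induced MET (decay) or under
#' sustained high IL-6 (rise): `value(t) = exp(+/- rate * t) * exp(e)`,
#' `e ~ N(0, sigma^2)`, on an even grid over `[0, t_max]`.
#'
#' @param rate True exponential rate (day^-1), > 0.
#' @param direction `"decay"` or `"rise"`.
#' @param sigma Log-scale noise sd (default 0.05).
#' @param n Number of points (default 20).
#' @param t_max Grid end (days); defaults to `3 / rate` so at least three
#'   e-foldings are observed.
#' @param seed Integer seed (default 1).
#' @return A `"marker_series"`: `times`, `values`, and the `spec`.
#' @export
gen_marker_series <- function(rate, direction = c("decay", "rise"),
                              sigma = 0.05, n = 20, t_max = NULL, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(rate > 0)
  if (is.null(t_max)) t_max <- 3 / rate
  spec <- synthetic_spec("marker_series",
                         list(rate = rate, direction = direction,
                              t_max = t_max),
                         sigma, n, seed)
  set.seed(seed)
  times <- seq(0, t_max, length.out = n)
  sgn <- if (direction == "decay") -1 else 1
  values <- exp(sgn * rate * times) * exp(stats::rnorm(n, 0, sigma))
  structure(list(times = times, values = values, spec = spec),
            class = "marker_series")
}

#' Generate two-state occupancy data from an exact CTMC
#'
#' Simulates each cell's EMT/MET path exactly (exponential holding times at
#' rates `lambda_met` out of EMT and `lambda_emt` out of MET) and records
#' state occupancy on an even grid. All cells start epithelial (MET), as in
#' a sorted-population experiment.
#'
#' @param rates A [transition_rates()] object.
#' @param n_cells Number of independent cells.
#' @param t_max Observation horizon (days).
#' @param seed Integer seed.
#' @param n_times Grid size (default 101).
#' @return A `"two_state_data"`: `times`, integer matrix `counts` with
#'   columns `EMT`/`MET`, per-cell `paths` (list of jump times/states),
#'   long-run `emt_time_fraction` (fraction of total cell-time spent EMT),
#'   and the `spec`.
#' @export
gen_two_state_data <- function(rates, n_cells = 100, t_max = 250, seed = 1,
                               n_times = 101) {
  stopifnot(inherits(rates, "transition_rates"), n_cells >= 1, t_max > 0)
  spec <- synthetic_spec("two_state",
                         list(lambda_emt = rates$lambda_emt,
                              lambda_met = rates$lambda_met,
                              n_cells = n_cells, t_max = t_max),
                         0, n_cells, seed)
  set.seed(seed)
  times <- seq(0, t_max, length.out = n_times)
  counts <- matrix(0L, nrow = n_times, ncol = 2L,
                   dimnames = list(NULL, c("EMT", "MET")))
  out_rate <- c(EMT = rates$lambda_met, MET = rates$lambda_emt)
  emt_time <- 0
  paths <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    t <- 0
    s <- "MET"
    jump_t <- 0
    jump_s <- s
    while (t < t_max) {
      hold <- stats::rexp(1, out_rate[[s]])
      t_end <- min(t + hold, t_max)
      idx <- which(times >= t & times < t_end)
      if (t_end >= t_max) idx <- c(idx, n_times)
      counts[idx, s] <- counts[idx, s] + 1L
      if (s == "EMT") emt_time <- emt_time + (t_end - t)
      t <- t + hold
      if (t < t_max) {
        s <- if (s == "EMT") "MET" else "EMT"
        jump_t <- c(jump_t, t)
        jump_s <- c(jump_s, s)
      }
    }
    paths[[i]] <- list(times = jump_t, states = jump_s)
  }
  structure(list(times = times, counts = counts, paths = paths,
                 emt_time_fraction = emt_time / (n_cells * t_max),
                 spec = spec),
            class = "two_state_data")
}

#' Generate noisy Gompertz growth observations
#'
#' [gompertz_value()] on an even grid times multiplicative log-normal noise.
#'
#' @param params A [gompertz_params()] object.
#' @param sigma Log-scale noise sd.
#' @param n Number of points.
#' @param t_max Grid end (days).
#' @param seed Integer seed.
#' @return List with `times`, `totals`, and the `spec`.
#' @export
gen_gompertz_data <- function(params, sigma = 0.01, n = 150, t_max = 4380,
                              seed = 1) {
  stopifnot(inherits(params, "gompertz_params"))
  spec <- synthetic_spec("gompertz",
                         list(A0 = params$A0, c_decay = params$c_decay,
                              N0 = params$N0, t_max = t_max),
                         sigma, n, seed)
  set.seed(seed)
  times <- seq(0, t_max, length.out = n)
  totals <- gompertz_value(params, times) * exp(stats::rnorm(n, 0, sigma))
  list(times = times, totals = totals, spec = spec)
}

#' Small fixture networks with known analytic behaviour
#'
#' Oracle substrates for validating the simulation engine:
#' \describe{
#'   \item{pure_death}{`A -> 0` at `rate`; mean `x0 exp(-rate t)`, variance
#'     `x0 exp(-rate t)(1 - exp(-rate t))`.}
#'   \item{birth_death}{`A -> 2A` at `b`, `A -> 0` at `delta`; mean
#'     `x0 exp((b - delta) t)`.}
#'   \item{dimerization}{`A + B <-> AB`; conserves the A- and B-moieties.}
#'   \item{two_state}{one particle hopping `EMT <-> MET`; long-run MET
#'     occupancy `lambda_met / (lambda_emt + lambda_met)`.}
#' }
#' Each network carries an `"analytic"` attribute with its closed-form
#' moment functions.
#'
#' @param b,delta Birth and death rates for the birth-death fixture.
#' @param death_rate Rate for the pure-death fixture.
#' @param x0 Initial count for the single-species fixtures.
#' @param lambda_emt,lambda_met Switch rates for the two-state fixture.
#' @return Named list of reaction networks.
#' @export
fixture_networks <- function(b = 2, delta = 1, death_rate = 1, x0 = 1000,
                             lambda_emt = 0.02, lambda_met = 0.08) {
  pure_death <- build_network(
    list(species("A", "cell", x0)),
    list(reaction("death", "A", character(0), death_rate, "death")))
  attr(pure_death, "analytic") <- list(
    mean = function(t) x0 * exp(-death_rate * t),
    var = function(t) x0 * exp(-death_rate * t) * (1 - exp(-death_rate * t)))

  birth_death <- build_network(
    list(species("A", "cell", x0)),
    list(reaction("birth", "A", c("A", "A"), b, "renewal"),
         reaction("death", "A", character(0), delta, "death")))
  attr(birth_death, "analytic") <- list(
    mean = function(t) x0 * exp((b - delta) * t),
    var = function(t) {
      if (b == delta) return(2 * b * x0 * t)
      x0 * (b + delta) / (b - delta) * exp((b - delta) * t) *
        (exp((b - delta) * t) - 1)
    })

  dimerization <- build_network(
    list(species("A", "cytokine", 100), species("B", "receptor", 100),
         species("AB", "complex", 0)),
    list(reaction("bind", c("A", "B"), "AB", 0.01, "binding"),
         reaction("unbind", "AB", c("A", "B"), 1, "dissociation")))

  two_state <- build_network(
    list(species("EMT", "cell", 0), species("MET", "cell", 1)),
    list(reaction("emt", "MET", "EMT", lambda_emt, "transition"),
         reaction("met", "EMT", "MET", lambda_met, "transition")))
  attr(two_state, "analytic") <- list(
    pi_met = lambda_met / (lambda_emt + lambda_met))

  list(pure_death = pure_death, birth_death = birth_death,
       dimerization = dimerization, two_state = two_state)
}

#' Write a synthetic dataset with its spec sidecar
#'
#' CSV of the data plus a JSON sidecar of the generating spec, so any
#' dataset can be regenerated exactly.
#'
#' @param data A `marker_series`, `two_state_data`, or Gompertz data list.
#' @param path CSV output path; the sidecar is `paste0(path, ".spec.json")`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(data, path) {
  df <- if (inherits(data, "marker_series")) {
    data.frame(time_days = data$times, expression = data$values)
  } else if (inherits(data, "two_state_data")) {
    data.frame(time_days = data$times, emt = data$counts[, "EMT"],
               met = data$counts[, "MET"])
  } else {
    data.frame(time_days = data$times, total_cells = data$totals)
  }
  utils::write.csv(df, path, row.names = FALSE)
  spec <- data$spec
  writeLines(.spec_json(spec), paste0(path, ".spec.json"))
  invisible(path)
}

#' Regenerate a dataset from a spec sidecar
#'
#' @param path CSV path previously written by [write_synthetic()].
#' @return The regenerated dataset (identical to the original).
#' @export
read_synthetic <- function(path) {
  spec <- .spec_from_json(paste0(path, ".spec.json"))
  p <- spec$params
  switch(spec$generator,
    marker_series = gen_marker_series(p$rate, p$direction, spec$sigma,
                                      spec$n, p$t_max, spec$seed),
    two_state = gen_two_state_data(
      transition_rates(p$lambda_emt, p$lambda_met),
      p$n_cells, p$t_max, spec$seed),
    gompertz = gen_gompertz_data(
      gompertz_params(p$A0, p$c_decay, p$N0), spec$sigma, spec$n,
      p$t_max, spec$seed),
    stop("unknown generator: ", spec$generator, call. = FALSE))
}

# tiny hand-rolled flat JSON (spec fields are scalars/flat lists); avoids a
# hard jsonlite dependency in the package core
.spec_json <- function(spec) {
  enc <- function(x) {
    if (is.character(x)) paste0('"', x, '"') else format(x, digits = 17)
  }
  par <- paste0('"', names(spec$params), '": ',
                vapply(spec$params, enc, character(1)), collapse = ", ")
  sprintf(
    '{"generator": "%s", "params": {%s}, "sigma": %s, "n": %s, "seed": %s}',
    spec$generator, par, format(spec$sigma, digits = 17), spec$n, spec$seed)
}

.spec_from_json <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  obj <- .parse_flat_json(txt)
  synthetic_spec(obj$generator, obj$params, as.numeric(obj$sigma),
                 as.numeric(obj$n), as.numeric(obj$seed))
}

.parse_flat_json <- function(txt) {
  # minimal parser for the flat objects written by .spec_json
  grab <- function(pat) {
    m <- regmatches(txt, regexec(pat, txt))[[1]]
    if (length(m) < 2L) NULL else m[2L]
  }
  params_txt <- grab('"params": \\{([^}]*)\\}')
  pairs <- strsplit(params_txt, ", ")[[1]]
  params <- list()
  for (p in pairs) {
    kv <- strsplit(p, ": ")[[1]]
    key <- gsub('"', "", kv[1])
    val <- kv[2]
    params[[key]] <- if (grepl('^"', val)) gsub('"', "", val) else as.numeric(val)
  }
  list(generator = grab('"generator": "([^"]*)"'),
       params = params,
       sigma = grab('"sigma": ([-0-9.e+]+)'),
       n = grab('"n": ([0-9]+)'),
       seed = grab('"seed": ([-0-9]+)'))
}
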
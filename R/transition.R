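# Two-state continuous-time Markov chain model of BCSC plasticity.
# State 1 = EMT (mesenchymal, CD44+/CD24-, quiescent), state 2 = MET
# (epithelial, ALDH+, proliferative). lambda_met is the rate OF the
# mesenchymal-to-epithelial transition (out of EMT), lambda_emt the rate of
# the epithelial-to-mesenchymal transition (out of MET). Detailed balance:
# pi_EMT * lambda_MET = pi_MET * lambda_EMT.

#' Equilibrium occupancy of the two BCSC states
#'
#' @param pi_emt Fraction of cells in the mesenchymal (EMT-like) state.
#' @return An `"equilibrium_distribution"` with components `pi_emt`,
#'   `pi_met` summing to one.
#' @export
equilibrium_distribution <- function(pi_emt) {
  stopifnot(pi_emt >= 0, pi_emt <= 1)
  structure(list(pi_emt = pi_emt, pi_met = 1 - pi_emt),
            class = "equilibrium_distribution")
}

#' EMT/MET interconversion rates
#'
#' @param lambda_emt Epithelial-to-mesenchymal rate (cell^-1 day^-1).
#' @param lambda_met Mesenchymal-to-epithelial rate (cell^-1 day^-1).
#' @return A `"transition_rates"` object.
#' @export
transition_rates <- function(lambda_emt, lambda_met) {
  stopifnot(lambda_emt > 0, lambda_met > 0)
  structure(list(lambda_emt = lambda_emt, lambda_met = lambda_met),
            class = "transition_rates")
}

#' Equilibrium distribution from marker frequencies
#'
#' Maps observed marker-positive frequencies (e.g. CD44+CD24- as the
#' mesenchymal numerator, ALDH+ as the epithelial one) to state occupancies:
#' `pi_emt = f_mes / (f_mes + f_epi)`.
#'
#' @param f_mesenchymal Observed mesenchymal-marker fraction (> 0).
#' @param f_epithelial Observed epithelial-marker fraction (> 0).
#' @return An [equilibrium_distribution()].
#' @examples
#' equilibrium_from_marker_fractions(0.008, 0.003)$pi_emt # ~0.73
#' @export
equilibrium_from_marker_fractions <- function(f_mesenchymal, f_epithelial) {
  if (f_mesenchymal < 0 || f_epithelial < 0 ||
      (f_mesenchymal + f_epithelial) <= 0) {
    stop("marker fractions must be positive", call. = FALSE)
  }
  equilibrium_distribution(f_mesenchymal / (f_mesenchymal + f_epithelial))
}

#' Epithelial occupancy implied by transition rates
#'
#' `pi_met = lambda_met / (lambda_emt + lambda_met)`.
#'
#' @param rates A [transition_rates()] object.
#' @return Fraction in the MET-like state.
#' @export
met_fraction_from_rates <- function(rates) {
  rates$lambda_met / (rates$lambda_emt + rates$lambda_met)
}

#' Complete the two-state chain via detailed balance
#'
#' Given the equilibrium occupancy and one of the two rates, solves the
#' stationary flux balance `pi_emt * lambda_met = pi_met * lambda_emt` for
#' the other.
#'
#' @param eq An [equilibrium_distribution()].
#' @param lambda_emt,lambda_met Exactly one of the two rates
#'   (cell^-1 day^-1).
#' @return A [transition_rates()] object.
#' @examples
#' complete_rates(equilibrium_distribution(0.2), lambda_met = 0.08)$lambda_emt
#' @export
complete_rates <- function(eq, lambda_emt = NULL, lambda_met = NULL) {
  stopifnot(inherits(eq, "equilibrium_distribution"))
  if (is.null(lambda_emt) == is.null(lambda_met)) {
    stop("supply exactly one of lambda_emt, lambda_met", call. = FALSE)
  }
  if (eq$pi_emt <= 0 || eq$pi_met <= 0) {
    stop("degenerate chain: an equilibrium component is zero", call. = FALSE)
  }
  if (is.null(lambda_emt)) {
    stopifnot(lambda_met > 0)
    transition_rates(lambda_emt = lambda_met * eq$pi_emt / eq$pi_met,
                     lambda_met = lambda_met)
  } else {
    stopifnot(lambda_emt > 0)
    transition_rates(lambda_emt = lambda_emt,
                     lambda_met = lambda_emt * eq$pi_met / eq$pi_emt)
  }
}

#' Estimate a transition rate from an exponential marker time course
#'
#' Fits `log(value) ~ time` by ordinary least squares and reports the slope
#' magnitude as the rate (an exponential-decay fit of vimentin after induced
#' MET gives an upper bound on the mesenchymal-to-epithelial rate; a rising
#' fit gives the reverse). Log-linear OLS is the default for determinism and
#' closed-form standard errors; `nonlinear = TRUE` refits
#' `value ~ A * exp(+/- rate * t)` by Levenberg-Marquardt starting from the
#' OLS solution.
#'
#' @param series A [gen_marker_series()] result, or a list/data frame with
#'   `times` (days) and `values` (positive expression levels).
#' @param direction `"decay"` or `"rise"`.
#' @param nonlinear Refit on the natural scale (default `FALSE`).
#' @return List with `rate` (day^-1), `se`, and the underlying `fit`.
#' @export
fit_exponential_rate <- function(series, direction = c("decay", "rise"),
                                 nonlinear = FALSE) {
  direction <- match.arg(direction)
  times <- series$times
  values <- series$values
  if (length(times) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  sgn <- if (direction == "decay") -1 else 1
  fit <- stats::lm(log(values) ~ times)
  slope <- unname(stats::coef(fit)[2L])
  # vcov warns on exactly collinear (noise-free) input; the zero SE is right
  se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))[2L]))
  rate <- sgn * slope
  if (nonlinear) {
    nl <- minpack.lm::nlsLM(
      values ~ A * exp(sgn * rate * times),
      start = list(A = exp(unname(stats::coef(fit)[1L])), rate = rate),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    rate <- unname(stats::coef(nl)[["rate"]])
    se <- unname(suppressWarnings(
      summary(nl)$coefficients["rate", "Std. Error"]))
    fit <- nl
  }
  list(rate = rate, se = se, fit = fit)
}

#' Convert a once-per-interval event frequency to a daily rate
#'
#' E.g. symmetric self-renewal observed about once every 42 weeks
#' corresponds to `1 / (42 * 7) = 0.0034` cell^-1 day^-1.
#'
#' @param weeks Mean interval between events, in weeks.
#' @return Rate in cell^-1 day^-1.
#' @export
rate_from_period_weeks <- function(weeks) {
  stopifnot(weeks > 0)
  1 / (weeks * 7)
}

#' Benchmark dedifferentiation rate from iPS reprogramming
#'
#' Reported comparison value: about 1% of fibroblasts reprogram over a
#' 28-day culture, quoted as 0.0036 cell^-1 day^-1. (Note 0.01/28 is
#' 0.00036; the quoted constant is kept as published and is used only as a
#' qualitative benchmark that EMT/MET interconversion is much faster than
#' dedifferentiation.)
#'
#' @format A single number (cell^-1 day^-1).
#' @export
ips_dedifferentiation_rate <- 0.0036

#' Round a rate for reporting
#'
#' Two significant figures, the reporting convention used throughout;
#' full precision is retained in all computations.
#'
#' @param x Numeric.
#' @return `signif(x, 2)`.
#' @export
report_rate <- function(x) signif(x, 2)
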
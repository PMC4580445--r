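# In-silico therapy screen: inhibit niche elements singly and in all
# pairwise combinations by scaling the affected reaction rate constants by
# 1e-10, simulate each condition with common random numbers, and rank
# conditions by how often the BCSC population is driven extinct.

#' An inhibition target
#'
#' @param name Target name.
#' @param affected_reactions Reaction labels whose rate constants the
#'   inhibitor scales (non-empty).
#' @param factor Multiplicative rate scaling, in (0, 1]; default 1e-10.
#' @return An `"inhibition_target"` object.
#' @export
inhibition_target <- function(name, affected_reactions, factor = 1e-10) {
  stopifnot(length(affected_reactions) >= 1L, factor > 0, factor <= 1)
  structure(list(name = name,
                 affected_reactions = as.character(affected_reactions),
                 factor = factor), class = "inhibition_target")
}

#' Default inhibition target set
#'
#' The nine inhibitable niche elements (IL-6, IL-8, TGF-beta, BMP, mir-93,
#' HER2, Akt, Stat3, Lin-28) with their affected channels from
#' [niche_inhibition_map()].
#'
#' @param factor Rate scaling applied on inhibition (default 1e-10).
#' @return Named list of [inhibition_target()] objects.
#' @export
default_inhibition_targets <- function(factor = 1e-10) {
  map <- niche_inhibition_map()
  stats::setNames(
    lapply(names(map), function(nm) inhibition_target(nm, map[[nm]], factor)),
    names(map))
}

.resolve_targets <- function(targets, factor = 1e-10) {
  if (inherits(targets, "inhibition_target")) targets <- list(targets)
  lapply(targets, function(tg) {
    if (inherits(tg, "inhibition_target")) return(tg)
    map <- niche_inhibition_map()
    if (!is.character(tg) || !(tg %in% names(map))) {
      stop("unknown inhibition target: ", tg, call. = FALSE)
    }
    inhibition_target(tg, map[[tg]], factor)
  })
}

#' Apply inhibitions to a network
#'
#' Returns a copy of the network in which each target's affected channels
#' have their rate constants multiplied by the target's factor. Initial
#' counts are untouched; untargeted channels are untouched.
#'
#' @param network A reaction network (typically [build_niche_model()]).
#' @param targets List of [inhibition_target()] objects and/or names from
#'   the default target set; empty list returns the network unchanged.
#' @param factor Scaling used when `targets` are given by name.
#' @return The inhibited network.
#' @export
apply_inhibition <- function(network, targets, factor = 1e-10) {
  targets <- .resolve_targets(targets, factor)
  for (tg in targets) {
    missing <- setdiff(tg$affected_reactions, names(network$rates))
    if (length(missing)) {
      stop("target '", tg$name, "' references unknown reaction '",
           missing[1L], "'", call. = FALSE)
    }
    network <- set_rates(
      network, network$rates[tg$affected_reactions] * tg$factor)
  }
  network
}

# radix sort: byte-wise ordering, independent of the session locale
.condition_label <- function(names) {
  paste(sort(names, method = "radix"), collapse = "+")
}

.cell_summary <- function(ens) {
  emt <- ens$arr[, , "EMT", drop = TRUE]
  met <- ens$arr[, , "MET", drop = TRUE]
  if (is.null(dim(emt))) { # single replicate
    emt <- matrix(emt, nrow = 1L)
    met <- matrix(met, nrow = 1L)
  }
  list(times = ens$times, n = ens$n,
       emt = emt, met = met, total = emt + met,
       emt_mean = colMeans(emt), met_mean = colMeans(met),
       total_mean = colMeans(emt + met))
}

#' Run the in-silico inhibition screen
#'
#' Simulates the baseline niche plus every single-target (or every unordered
#' pairwise) inhibition condition, with common random numbers across
#' conditions (each condition reuses the same per-replicate seeds), and
#' collects BCSC trajectories and extinction statistics.
#'
#' @param network Baseline network (default [build_niche_model()]).
#' @param targets Targets to screen (default the nine-element set).
#' @param mode `"single"` or `"pairwise"`.
#' @param horizon_days Simulation horizon (default 1000).
#' @param reps Replicates per condition (default 100).
#' @param settings [leap_settings()]; `rng_seed` is the common root seed.
#' @param times Recording grid (default 101 points).
#' @param factor Inhibition factor for named targets.
#' @return A `"screen_result"`: `conditions` data frame (condition,
#'   extinction frequencies at the horizon, mean counts at the horizon),
#'   per-condition `cells` summaries (EMT/MET/total replicate matrices and
#'   means), `horizon_days`, `reps`, `mode`.
#' @export
run_screen <- function(network = build_niche_model(),
                       targets = default_inhibition_targets(),
                       mode = c("single", "pairwise"),
                       horizon_days = 1000, reps = 100,
                       settings = leap_settings(rng_seed = 1),
                       times = NULL, factor = 1e-10) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  targets <- .resolve_targets(targets, factor)
  names(targets) <- vapply(targets, function(t) t$name, character(1))
  combos <- if (mode == "single") {
    lapply(names(targets), function(nm) nm)
  } else {
    utils::combn(names(targets), 2L, simplify = FALSE)
  }
  conds <- c(list(character(0)), combos)
  labels <- vapply(conds, function(cc) {
    if (!length(cc)) "baseline" else .condition_label(cc)
  }, character(1))
  times <- .rec_times(horizon_days, times)
  cells <- vector("list", length(conds))
  names(cells) <- labels
  for (i in seq_along(conds)) {
    net_i <- if (length(conds[[i]])) {
      apply_inhibition(network, targets[conds[[i]]])
    } else {
      network
    }
    ens <- simulate_ensemble(net_i, horizon_days, settings, n = reps,
                             times = times)
    cells[[i]] <- .cell_summary(ens)
  }
  res <- structure(list(cells = cells, horizon_days = horizon_days,
                        reps = reps, mode = mode, times = times),
                   class = "screen_result")
  res$conditions <- data.frame(
    condition = labels,
    extinction_emt = vapply(labels, function(l) {
      extinction_frequency(res, "EMT", condition = l)
    }, numeric(1)),
    extinction_met = vapply(labels, function(l) {
      extinction_frequency(res, "MET", condition = l)
    }, numeric(1)),
    extinction_total = vapply(labels, function(l) {
      extinction_frequency(res, "total", condition = l)
    }, numeric(1)),
    mean_total_at_horizon = vapply(labels, function(l) {
      cl <- res$cells[[l]]
      cl$total_mean[length(cl$total_mean)]
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: ", x$mode, " mode, ", nrow(x$conditions),
      " conditions (incl. baseline), ", x$reps, " replicates, horizon ",
      x$horizon_days, " days\n", sep = "")
  invisible(x)
}

#' Extinction frequency of a BCSC population
#'
#' Fraction of replicates in which the selected population has reached zero
#' by `at_day` (first passage on the recording grid); once the total BCSC
#' count hits zero it can never recover, so the total-frequency is
#' non-decreasing in time by construction, and the first-passage convention
#' extends that monotonicity to the per-state counts.
#'
#' @param result A [run_screen()] result.
#' @param population `"EMT"`, `"MET"`, or `"total"`.
#' @param at_day Evaluation day (default the horizon).
#' @param condition Condition label (default `"baseline"`).
#' @return Fraction in `[0, 1]`.
#' @export
extinction_frequency <- function(result, population = c("total", "EMT", "MET"),
                                 at_day = NULL, condition = "baseline") {
  population <- match.arg(population)
  if (is.null(at_day)) at_day <- result$horizon_days
  stopifnot(at_day <= result$horizon_days)
  cl <- result$cells[[condition]]
  if (is.null(cl)) stop("unknown condition: ", condition, call. = FALSE)
  m <- switch(population, EMT = cl$emt, MET = cl$met, total = cl$total)
  keep <- which(cl$times <= at_day + 1e-9)
  mean(apply(m[, keep, drop = FALSE] == 0, 1L, any))
}

#' Rank screen conditions by effectiveness
#'
#' Primary key: total-BCSC extinction frequency at the horizon (descending);
#' ties broken by mean total BCSC at the horizon (ascending), then by
#' condition label (lexicographic). Baseline is excluded from the ranking.
#'
#' @param result A [run_screen()] result.
#' @return The `conditions` data frame, best condition first.
#' @export
rank_combinations <- function(result) {
  df <- result$conditions[result$conditions$condition != "baseline", ]
  df[order(-df$extinction_total, df$mean_total_at_horizon, df$condition,
           method = "radix"), , drop = FALSE]
}

#' Parameter sensitivity sweep
#'
#' Re-simulates the niche (baseline or under combined HER2 + IL-6 blockade)
#' while varying either the epithelial-to-mesenchymal transition rate
#' constant (both EMT-direction channels) or the death rate of proliferating
#' epithelial BCSCs, one ensemble per value.
#'
#' @param network Baseline network.
#' @param parameter `"lambda_emt"` or `"met_death"`.
#' @param values Rate-constant values to sweep (non-empty).
#' @param condition `"baseline"` or `"HER2+IL6"`.
#' @param reps Replicates per value.
#' @param horizon_days Simulation horizon.
#' @param settings [leap_settings()]; common root seed across values.
#' @param times Recording grid.
#' @return A `"sensitivity_sweep"`: `values`, per-value cell summaries
#'   (`sweeps`), `parameter`, `condition`.
#' @export
sensitivity_sweep <- function(network = build_niche_model(),
                              parameter = c("lambda_emt", "met_death"),
                              values, condition = c("baseline", "HER2+IL6"),
                              reps = 100, horizon_days = 1000,
                              settings = leap_settings(rng_seed = 1),
                              times = NULL) {
  parameter <- match.arg(parameter)
  condition <- match.arg(condition)
  stopifnot(length(values) >= 1L)
  base <- if (condition == "HER2+IL6") {
    apply_inhibition(network, c("HER2", "IL6"))
  } else {
    network
  }
  times <- .rec_times(horizon_days, times)
  sweeps <- vector("list", length(values))
  for (i in seq_along(values)) {
    net_i <- switch(parameter,
      lambda_emt = set_rates(base, c(EMT_by_IL6_gp130 = values[i],
                                     EMT_by_TGFb = values[i])),
      met_death = set_rates(base, c(MET_death = values[i])))
    ens <- simulate_ensemble(net_i, horizon_days, settings, n = reps,
                             times = times)
    sweeps[[i]] <- .cell_summary(ens)
  }
  structure(list(values = values, sweeps = sweeps, parameter = parameter,
                 condition = condition, horizon_days = horizon_days),
            class = "sensitivity_sweep")
}

#' Mean total BCSC count at the horizon for each swept value
#'
#' @param sweep A [sensitivity_sweep()] result.
#' @return Numeric vector aligned with `sweep$values`.
#' @export
sweep_total_at_horizon <- function(sweep) {
  vapply(sweep$sweeps, function(cl) {
    cl$total_mean[length(cl$total_mean)]
  }, numeric(1))
}

#' Total-BCSC extinction fraction at the horizon for each swept value
#'
#' @param sweep A [sensitivity_sweep()] result.
#' @return Numeric vector aligned with `sweep$values`.
#' @export
sweep_extinction_at_horizon <- function(sweep) {
  vapply(sweep$sweeps, function(cl) {
    mean(apply(cl$total == 0, 1L, any))
  }, numeric(1))
}
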
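#!/usr/bin/env Rscript
# Single-target niche blockade: each of the nine inhibitable elements is
# knocked down (rate constants x 1e-10) on its own and the BCSC
# trajectories compared with baseline over 1000 days.

suppressPackageStartupMessages(library(bcscniche))
dir.create("results", showWarnings = FALSE)

res <- run_screen(build_niche_model(), default_inhibition_targets(),
                  mode = "single", horizon_days = 1000, reps = 100,
                  settings = leap_settings(rng_seed = 3001))
print(res)

nT <- length(res$times)
tab <- res$conditions
tab$mean_met_at_horizon <- sapply(tab$condition, function(l) {
  res$cells[[l]]$met_mean[nT]
})
tab$mean_emt_at_horizon <- sapply(tab$condition, function(l) {
  res$cells[[l]]$emt_mean[nT]
})
print(tab[order(tab$mean_total_at_horizon), ], digits = 3)

base <- res$cells$baseline
cat(sprintf("\nIL-6 blockade raises the MET-like mean at day 1000: %.3g vs baseline %.3g\n",
            res$cells$IL6$met_mean[nT], base$met_mean[nT]))
cat("no single blockade eradicates the BCSC pool (all extinction frequencies zero):",
    all(tab$extinction_total == 0), "\n")

write.csv(tab, "results/03_single_screen.csv", row.names = FALSE)

# per-condition mean trajectories for plotting
traj <- do.call(rbind, lapply(tab$condition, function(l) {
  cl <- res$cells[[l]]
  data.frame(condition = l, time_days = cl$times, emt_mean = cl$emt_mean,
             met_mean = cl$met_mean, total_mean = cl$total_mean)
}))
write.csv(traj, "results/03_single_trajectories.csv", row.names = FALSE)
cat("wrote results/03_single_screen.csv, 03_single_trajectories.csv\n")
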
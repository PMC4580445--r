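# shared helpers: tiny networks and Monte-Carlo error utilities

two_state_net <- function(lambda_emt = 0.02, lambda_met = 0.08, n_cells = 1) {
  build_network(
    list(species("EMT", "cell", 0), species("MET", "cell", n_cells)),
    list(reaction("emt", "MET", "EMT", lambda_emt, "transition"),
         reaction("met", "EMT", "MET", lambda_met, "transition")))
}

# standard error of an ensemble mean from the replicate matrix column
se_mean <- function(v) stats::sd(v) / sqrt(length(v))

expect_within_3se <- function(observed_mean, expected, se) {
  expect_lt(abs(observed_mean - expected), 3 * se + 1e-12)
}
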
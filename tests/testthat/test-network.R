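test_that("stoichiometry matrix is built from reactant/product multisets", {
  death <- build_network(list(species("A", "cell", 10)),
                         list(reaction("d", "A", character(0), 1, "death")))
  expect_equal(unname(death$nu[, 1]), -1)

  dimer <- build_network(
    list(species("A"), species("B"), species("AB")),
    list(reaction("bind", c("A", "B"), "AB", 0.01, "binding")))
  expect_equal(unname(dimer$nu[, "bind"]), c(-1, -1, 1))

  # catalytic channel leaves the catalyst unchanged
  cat_net <- build_network(
    list(species("MET", "cell", 1), species("actb")),
    list(reaction("renew", c("MET", "actb"), c("MET", "MET", "actb"),
                  1e-4, "renewal")))
  expect_equal(unname(cat_net$nu[, 1]), c(1, 0))
})

test_that("network definition errors are caught", {
  expect_error(
    build_network(list(species("A"), species("A")),
                  list(reaction("d", "A", character(0), 1, "death"))),
    "duplicate species")
  expect_error(
    build_network(list(species("A")),
                  list(reaction("d", "B", character(0), 1, "death"))),
    "unknown species")
  expect_error(reaction("t", c("A", "A", "A"), "B", 1), "termolecular")
  expect_error(reaction("t", "A", "B", -1), "rate constant")
  expect_error(species("A", initial_count = -2), "non-negative")
})

test_that("mass-action propensities follow reactant counts", {
  net <- build_network(
    list(species("A", "cell", 1000), species("B", "cell", 100),
         species("AB")),
    list(reaction("d", "A", character(0), 1.0, "death"),
         reaction("bind", c("A", "B"), "AB", 0.01, "binding"),
         reaction("homo", c("B", "B"), "AB", 0.1, "binding")))
  expect_equal(propensity(net, c(A = 1000, B = 100, AB = 0), "d"), 1000)
  expect_equal(propensity(net, c(A = 10, B = 100, AB = 0), "bind"),
               0.01 * 10 * 100)
  expect_equal(propensity(net, c(A = 0, B = 100, AB = 0), "bind"), 0)
  # homodimerization uses x(x-1)/2 pairs
  expect_equal(propensity(net, c(A = 0, B = 4, AB = 0), "homo"),
               0.1 * 4 * 3 / 2)
  expect_equal(propensity(net, c(A = 0, B = 0, AB = 0), "homo"), 0)
})

test_that("propensity is homogeneous of degree 1 in the rate constant", {
  net <- build_niche_model()
  x <- initial_state(net) + 5 # make complexes non-empty
  r0 <- propensities(net, x)
  for (s in c(1e-10, 0.5, 7)) {
    net_s <- set_rates(net, net$rates * s)
    expect_equal(propensities(net_s, x), r0 * s, tolerance = 1e-12)
  }
})

test_that("applying a reaction column equals removing reactants, adding products", {
  net <- build_niche_model()
  x <- initial_state(net) + 1
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    manual <- x
    for (s in r$reactants) manual[s] <- manual[s] - 1
    for (s in r$products) manual[s] <- manual[s] + 1
    expect_equal(x + net$nu[, j], manual)
  }
})

test_that("conserved moieties satisfy w'nu = 0 and binding pairs are conserved", {
  dimer <- build_network(
    list(species("A", "cytokine", 10), species("B", "receptor", 10),
         species("AB", "complex", 0)),
    list(reaction("bind", c("A", "B"), "AB", 0.01, "binding"),
         reaction("unbind", "AB", c("A", "B"), 1, "dissociation")))
  w <- conserved_moieties(dimer)
  expect_gt(ncol(w), 0)
  for (k in seq_len(ncol(w))) {
    expect_true(is_conserved(dimer, w[, k]))
  }
  # the A-moiety weighting is conserved
  expect_true(is_conserved(dimer, c(A = 1, AB = 1)))
  expect_true(is_conserved(dimer, c(B = 1, AB = 1)))
  expect_false(is_conserved(dimer, c(A = 1)))
})

test_that("set_rates validates labels and updates reactions", {
  net <- build_niche_model()
  net2 <- set_rates(net, c(MET_death = 0.5))
  expect_equal(unname(net2$rates[["MET_death"]]), 0.5)
  expect_equal(net2$reactions[[which(names(net2$rates) == "MET_death")]]$rate,
               0.5)
  expect_error(set_rates(net, c(nonexistent = 1)), "unknown reaction label")
})
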
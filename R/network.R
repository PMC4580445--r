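#' Define a reactant species
#'
#' A species is one countable entity in a reaction network: a cell
#' population, a cytokine, a receptor, a ligand-receptor complex, or an
#' intracellular signal. Counts are particle numbers, not concentrations.
#'
#' @param name Identifier, unique within a network. ASCII identifiers are
#'   recommended (e.g. `"IL6_gp130"`); display names can be carried separately.
#' @param category One of `"cell"`, `"cytokine"`, `"receptor"`, `"complex"`,
#'   `"intracellular-signal"`.
#' @param initial_count Non-negative integer particle count at time zero.
#' @return An object of class `"species"`.
#' @seealso [reaction()], [build_network()]
#' @export
species <- function(name, category = c("intracellular-signal", "cell",
                                       "cytokine", "receptor", "complex"),
                    initial_count = 0) {
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(initial_count) != 1L || is.na(initial_count) ||
      initial_count < 0 || initial_count != round(initial_count)) {
    stop("initial_count must be a single non-negative integer", call. = FALSE)
  }
  structure(list(name = name, category = category,
                 initial_count = as.numeric(initial_count)),
            class = "species")
}

#' Define a mass-action reaction channel
#'
#' Reactants and products are given as character vectors of species names;
#' multiplicity is expressed by repetition (`c("A", "A")` for `2A`). Catalytic
#' channels list the catalyst on both sides, so its net stoichiometry is zero.
#' At most two reactant molecules are allowed (no termolecular channels).
#'
#' @param label Identifier, unique within a network.
#' @param reactants Character vector of reactant species names (possibly
#'   empty for a zero-order source).
#' @param products Character vector of product species names (possibly empty
#'   for a degradation/death channel).
#' @param rate Mass-action rate constant `a_j`: day^-1 for zero/first-order
#'   channels, particle^-1 day^-1 for second-order channels.
#' @param category One of `"binding"`, `"dissociation"`, `"signaling"`,
#'   `"transition"`, `"renewal"`, `"death"`, `"transcription"`.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(label, reactants, products, rate,
                     category = c("signaling", "binding", "dissociation",
                                  "transition", "renewal", "death",
                                  "transcription")) {
  category <- match.arg(category)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  reactants <- as.character(reactants)
  products <- as.character(products)
  if (length(reactants) > 2L) {
    stop("no termolecular channels: at most 2 reactant molecules", call. = FALSE)
  }
  if (length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("rate constant must be a single non-negative number", call. = FALSE)
  }
  structure(list(label = label, reactants = reactants, products = products,
                 rate = as.numeric(rate), category = category),
            class = "reaction")
}

#' Build a validated reaction network
#'
#' Assembles species and reaction channels into a network with its `d x c`
#' stoichiometry matrix `nu`, where column `j` is the increment vector of
#' channel `j`: `nu[k, j]` is the multiplicity of species `k` among the
#' products of `j` minus its multiplicity among the reactants.
#'
#' @param species List of [species()] objects (the `d` reactant species).
#' @param reactions List of [reaction()] objects (the `c` channels).
#' @return An object of class `"reaction_network"` with elements
#'   `species` (data frame: name, category, initial_count), `reactions`
#'   (list of reactions), `rates` (named vector of rate constants),
#'   `nu` (stoichiometry matrix), and internal reactant index tables.
#' @examples
#' net <- build_network(
#'   list(species("A", initial_count = 10), species("B", initial_count = 100),
#'        species("AB")),
#'   list(reaction("bind", c("A", "B"), "AB", 0.01, "binding"),
#'        reaction("unbind", "AB", c("A", "B"), 1, "dissociation"))
#' )
#' net$nu
#' @export
build_network <- function(species, reactions) {
  if (inherits(species, "species")) species <- list(species)
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(length(species) >= 1L, length(reactions) >= 1L)
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate species name: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  labels <- vapply(reactions, function(r) r$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate reaction label: ", labels[duplicated(labels)][1L],
         call. = FALSE)
  }
  d <- length(nm)
  c_ <- length(reactions)
  nu <- matrix(0L, nrow = d, ncol = c_, dimnames = list(nm, labels))
  # reactant index table: up to two reactant molecule slots per channel (NA = empty)
  ridx <- matrix(NA_integer_, nrow = 2L, ncol = c_, dimnames = list(NULL, labels))
  for (j in seq_len(c_)) {
    r <- reactions[[j]]
    for (who in c("reactants", "products")) {
      unknown <- setdiff(r[[who]], nm)
      if (length(unknown)) {
        stop("reaction '", r$label, "' references unknown species '",
             unknown[1L], "'", call. = FALSE)
      }
    }
    for (s in r$reactants) nu[s, j] <- nu[s, j] - 1L
    for (s in r$products) nu[s, j] <- nu[s, j] + 1L
    ri <- match(r$reactants, nm)
    if (length(ri)) ridx[seq_along(ri), j] <- ri
  }
  structure(list(
    species = data.frame(
      name = nm,
      category = vapply(species, function(s) s$category, character(1)),
      initial_count = vapply(species, function(s) s$initial_count, numeric(1)),
      stringsAsFactors = FALSE),
    reactions = reactions,
    rates = stats::setNames(vapply(reactions, function(r) r$rate, numeric(1)),
                            labels),
    nu = nu,
    reactant_index = ridx
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network: ", nrow(x$species), " species, ",
      length(x$reactions), " channels\n", sep = "")
  tab <- table(vapply(x$reactions, function(r) r$category, character(1)))
  cat("channels by category:",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Initial state of a network
#'
#' @param network A [build_network()] object.
#' @return Named numeric vector of initial particle counts.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$initial_count, network$species$name)
}

#' Replace rate constants by reaction label
#'
#' @param network A reaction network.
#' @param rates Named numeric vector; names must be reaction labels.
#' @return The network with updated rate constants.
#' @export
set_rates <- function(network, rates) {
  unknown <- setdiff(names(rates), names(network$rates))
  if (length(unknown)) {
    stop("unknown reaction label: ", unknown[1L], call. = FALSE)
  }
  network$rates[names(rates)] <- as.numeric(rates)
  for (j in seq_along(network$reactions)) {
    network$reactions[[j]]$rate <-
      unname(network$rates[[network$reactions[[j]]$label]])
  }
  network
}

#' Mass-action propensity of one channel
#'
#' Returns the instantaneous firing rate `r_j(x)` of channel `j` in state
#' `x`: `a_j` for a zero-order source, `a_j * x_k` for a unimolecular channel
#' on species `k`, `a_j * x_k * x_m` for a bimolecular channel on distinct
#' species, and `a_j * x_k * (x_k - 1) / 2` for a homodimerization. The
#' propensity is zero whenever a reactant is absent.
#'
#' @param network A reaction network.
#' @param state Named or ordered numeric vector of current counts.
#' @param j Channel index (1-based) or reaction label.
#' @return Non-negative rate in day^-1.
#' @export
propensity <- function(network, state, j) {
  if (is.character(j)) j <- match(j, names(network$rates))
  stopifnot(!is.na(j), j >= 1L, j <= length(network$reactions))
  propensities(network, state)[j]
}

#' Propensities of all channels
#'
#' @inheritParams propensity
#' @return Numeric vector of length `c` (one rate per channel, day^-1).
#' @export
propensities <- function(network, state) {
  x <- as.numeric(state)
  a <- unname(network$rates)
  ri <- network$reactant_index
  r <- a
  for (j in seq_along(a)) {
    i1 <- ri[1L, j]; i2 <- ri[2L, j]
    if (!is.na(i1)) {
      if (is.na(i2)) {
        r[j] <- a[j] * x[i1]
      } else if (i1 == i2) {
        r[j] <- a[j] * x[i1] * (x[i1] - 1) / 2
      } else {
        r[j] <- a[j] * x[i1] * x[i2]
      }
    }
  }
  pmax(r, 0)
}

#' Conserved moieties of a network
#'
#' Finds integer weight vectors `w` with `t(w) %*% nu = 0`; the weighted
#' count `sum(w * x)` is then invariant under every reaction channel (e.g.
#' total receptor = free receptor + ligand-bound receptor). The basis is
#' obtained from the rational null space of `t(nu)` and scaled to smallest
#' integers.
#'
#' @param network A reaction network.
#' @return Integer matrix with one conservation vector per column (possibly
#'   zero columns), rownames = species names.
#' @export
conserved_moieties <- function(network) {
  ns <- .nullspace_rational(t(network$nu))
  if (ncol(ns) == 0L) {
    return(matrix(integer(0), nrow = nrow(network$nu), ncol = 0L,
                  dimnames = list(rownames(network$nu), NULL)))
  }
  rownames(ns) <- rownames(network$nu)
  ns
}

#' Test whether a weighting is conserved
#'
#' @param network A reaction network.
#' @param w Numeric vector of per-species weights (length `d`, or named).
#' @return `TRUE` if `t(w) %*% nu` is exactly zero for every channel.
#' @export
is_conserved <- function(network, w) {
  if (!is.null(names(w))) {
    full <- stats::setNames(numeric(nrow(network$nu)), rownames(network$nu))
    full[names(w)] <- w
    w <- full
  }
  all(abs(as.numeric(crossprod(w, network$nu))) < 1e-9)
}

# Rational null space of M via reduced row echelon form; columns scaled to
# smallest integers (entries in stoichiometric problems are small rationals).
.nullspace_rational <- function(M, tol = 1e-9) {
  M <- as.matrix(M) * 1.0
  m <- nrow(M); n <- ncol(M)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(M[row:m, col])) + row - 1L
    if (abs(M[p, col]) < tol) next
    if (p != row) M[c(p, row), ] <- M[c(row, p), ]
    M[row, ] <- M[row, ] / M[row, col]
    for (r in seq_len(m)) {
      if (r != row && abs(M[r, col]) > tol) {
        M[r, ] <- M[r, ] - M[r, col] * M[row, ]
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- matrix(0, nrow = n, ncol = length(free))
  for (i in seq_along(free)) {
    f <- free[i]
    v <- numeric(n)
    v[f] <- 1
    if (length(pivots)) {
      v[pivots] <- -M[seq_along(pivots), f]
    }
    basis[, i] <- .to_smallest_integers(v)
  }
  basis
}

.to_smallest_integers <- function(v, max_den = 1000L, tol = 1e-6) {
  for (q in seq_len(max_den)) {
    if (all(abs(q * v - round(q * v)) < tol)) {
      w <- round(q * v)
      g <- Reduce(.gcd, abs(w[w != 0]))
      if (length(g) && g > 1) w <- w / g
      if (sum(w) < 0) w <- -w
      return(as.integer(w))
    }
  }
  v
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
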
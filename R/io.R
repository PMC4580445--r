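# Interchange formats: a deliberately small SBML Level 3 core subset
# (species with initial amounts, irreversible reactions with a single
# mass-action rate constant as a local parameter) and a YAML config format.
# The SBML writer/reader covers exactly what this package's networks
# contain; it is not a general SBML implementation.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"

#' Export a reaction network to SBML Level 3
#'
#' Writes species (with initial amounts, in particle numbers), reactions
#' (with stoichiometries), and mass-action rate constants (as the local
#' parameter `k` of each kinetic law). Species and reaction categories are
#' carried in `notes` elements so the file round-trips through
#' [read_sbml()].
#'
#' @param network A reaction network.
#' @param path Output file path.
#' @param model_id Model identifier.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, model_id = "network") {
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns,
                            level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "niche", constant = "true",
                      spatialDimensions = "3", size = "1")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species))) {
    s <- xml2::xml_add_child(
      sps, "species",
      id = network$species$name[i], compartment = "niche",
      initialAmount = format(network$species$initial_count[i], digits = 17),
      hasOnlySubstanceUnits = "true", boundaryCondition = "false",
      constant = "false")
    .sbml_notes(s, network$species$category[i])
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rx <- xml2::xml_add_child(rxns, "reaction", id = r$label,
                              reversible = "false", fast = "false")
    .sbml_notes(rx, r$category)
    for (side in c("reactants", "products")) {
      who <- r[[side]]
      if (!length(who)) next
      lst <- xml2::xml_add_child(
        rx, if (side == "reactants") "listOfReactants" else "listOfProducts")
      tab <- table(who)
      for (nm in names(tab)) {
        xml2::xml_add_child(lst, "speciesReference", species = nm,
                            stoichiometry = as.character(unname(tab[[nm]])),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "k",
                        value = format(r$rate, digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_notes <- function(node, category) {
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  p <- xml2::xml_add_child(body, "p")
  xml2::xml_set_text(p, paste0("category: ", category))
}

.sbml_category <- function(node, default) {
  p <- xml2::xml_find_first(node, ".//*[local-name() = 'p']")
  if (inherits(p, "xml_missing")) return(default)
  txt <- xml2::xml_text(p)
  if (grepl("^category: ", txt)) sub("^category: ", "", txt) else default
}

#' Import a reaction network from SBML Level 3
#'
#' Reads the subset written by [write_sbml()]: species initial amounts,
#' reaction stoichiometries, and the mass-action rate constant `k` of each
#' kinetic law. Round-trips preserve species, reactions, rate constants,
#' and initial amounts exactly.
#'
#' @param path SBML file path.
#' @return A reaction network.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name() = '%s']", name))
  }
  sp_nodes <- find_all(doc, "species")
  if (!length(sp_nodes)) stop("no species found in ", path, call. = FALSE)
  sp <- lapply(sp_nodes, function(s) {
    species(xml2::xml_attr(s, "id"),
            .sbml_category(s, "intracellular-signal"),
            as.numeric(xml2::xml_attr(s, "initialAmount")))
  })
  rx_nodes <- find_all(doc, "reaction")
  rx <- lapply(rx_nodes, function(r) {
    side <- function(list_name) {
      refs <- xml2::xml_find_all(
        r, sprintf(".//*[local-name() = '%s']/*[local-name() = 'speciesReference']",
                   list_name))
      unlist(lapply(refs, function(ref) {
        k <- xml2::xml_attr(ref, "stoichiometry")
        k <- if (is.na(k)) 1L else as.integer(as.numeric(k))
        rep(xml2::xml_attr(ref, "species"), k)
      }))
    }
    kpar <- xml2::xml_find_first(
      r, ".//*[local-name() = 'localParameter' and @id = 'k']")
    if (inherits(kpar, "xml_missing")) {
      stop("reaction '", xml2::xml_attr(r, "id"),
           "' has no rate constant parameter 'k'", call. = FALSE)
    }
    reactants <- side("listOfReactants")
    products <- side("listOfProducts")
    reaction(xml2::xml_attr(r, "id"),
             if (is.null(reactants)) character(0) else reactants,
             if (is.null(products)) character(0) else products,
             as.numeric(xml2::xml_attr(kpar, "value")),
             .sbml_category(r, "signaling"))
  })
  build_network(sp, rx)
}

#' Export a reaction network to a YAML config
#'
#' Sections: `species` (name/category), `reactions` (label, reactants,
#' products, category), `rates` (label -> constant), `initial_counts`, and
#' optionally `inhibition_map`.
#'
#' @param network A reaction network.
#' @param path Output path.
#' @param inhibition_map Optional named list of target -> reaction labels.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(network, path, inhibition_map = NULL) {
  cfg <- list(
    species = lapply(seq_len(nrow(network$species)), function(i) {
      list(name = network$species$name[i],
           category = network$species$category[i])
    }),
    reactions = lapply(network$reactions, function(r) {
      list(label = r$label, reactants = as.list(r$reactants),
           products = as.list(r$products), category = r$category)
    }),
    rates = as.list(network$rates),
    initial_counts = as.list(stats::setNames(network$species$initial_count,
                                             network$species$name)))
  if (!is.null(inhibition_map)) cfg$inhibition_map <- inhibition_map
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Import a reaction network from a YAML config
#'
#' @param path YAML file written by [write_network_yaml()] (or by hand in
#'   the same layout).
#' @return A reaction network; any `inhibition_map` section is attached as
#'   the `"inhibition_map"` attribute.
#' @export
read_network_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("species", "reactions", "rates", "initial_counts")) {
    if (is.null(cfg[[sec]])) stop("missing config section: ", sec,
                                  call. = FALSE)
  }
  init <- cfg$initial_counts
  sp <- lapply(cfg$species, function(s) {
    species(s$name, s$category, init[[s$name]] %||% 0)
  })
  rx <- lapply(cfg$reactions, function(r) {
    rate <- cfg$rates[[r$label]]
    if (is.null(rate)) stop("missing rate constant for reaction '",
                            r$label, "'", call. = FALSE)
    reaction(r$label, unlist(r$reactants) %||% character(0),
             unlist(r$products) %||% character(0), rate, r$category)
  })
  net <- build_network(sp, rx)
  if (!is.null(cfg$inhibition_map)) {
    attr(net, "inhibition_map") <- lapply(cfg$inhibition_map, unlist)
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
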
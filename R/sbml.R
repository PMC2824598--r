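# Minimal SBML Level 3 writer/reader for the mass-action models (no SBML
# package is available in R, so the document is assembled and parsed with
# xml2). Only what these models need is supported: irreversible reactions
# with mass-action kinetic laws of the form k * reactant products.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

#' Export a network and parameter set as SBML
#'
#' One SBML species per model species (initial concentrations from the
#' default initial state), one parameter per rate constant, one
#' irreversible reaction per table row with its mass-action kinetic law in
#' MathML. Delayed reactions are not representable and are refused.
#'
#' @param network a [build_network()] object (no delay).
#' @param params a `param_set` with every rate populated.
#' @param file optional path; when given, the document is written there.
#' @return the SBML document as a character string (invisibly when `file`
#'   is given).
#' @export
export_sbml <- function(network, params, file = NULL) {
  if (any(network$delays > 0))
    stop("delayed reactions cannot be represented in this SBML export")
  if (any(!is.finite(params$k)))
    stop("parameter set is incomplete (non-finite rate constants)")
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3",
                            version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("p53_mdm2_mdmx_", network$variant))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  y0 <- default_initial_state(network, params$promoter_total)
  lsp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(network$n_species)) {
    xml2::xml_add_child(lsp, "species", id = paste0("x", i),
                        name = network$species$name[i],
                        compartment = "cell",
                        initialConcentration = format(y0[i], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lpar <- xml2::xml_add_child(model, "listOfParameters")
  used <- unique(network$rate_symbol)
  for (s in used) {
    xml2::xml_add_child(lpar, "parameter", id = s,
                        value = format(params$k[[s]], digits = 17),
                        constant = "true")
  }
  lrx <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(network$n_reactions)) {
    r <- network$reactions[[j]]
    rx <- xml2::xml_add_child(lrx, "reaction",
                              id = paste0("r", r$id),
                              reversible = "false")
    add_refs <- function(tag, idx) {
      if (length(idx) == 0) return()
      lst <- xml2::xml_add_child(rx, tag)
      for (i in unique(idx)) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("x", i),
                            stoichiometry = as.character(sum(idx == i)),
                            constant = "true")
      }
    }
    add_refs("listOfReactants", r$re)
    add_refs("listOfProducts", r$pr)
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .mathml_ns)
    terms <- c(r$sym, paste0("x", r$re))
    if (length(terms) == 1) {
      xml2::xml_add_child(math, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }
  txt <- as.character(doc)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Import an SBML document written by [export_sbml()]
#'
#' Reconstructs the species list, reaction structure (with the mass-action
#' rate symbol taken from the kinetic law), rate-constant vector and
#' initial state. The result carries the same `reaction_network` interface
#' used by [network_rhs()], so exported and re-imported models can be
#' compared state-by-state.
#'
#' @param x SBML text or a file path.
#' @return list(network, k, initial_state).
#' @export
import_sbml <- function(x) {
  doc <- if (length(x) == 1 && !grepl("<", x[1]) && file.exists(x[1]))
    xml2::read_xml(x) else xml2::read_xml(paste(x, collapse = "\n"))
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  n_sp <- length(sp_ids)
  y0 <- setNames(as.numeric(xml2::xml_attr(sp_nodes,
                                           "initialConcentration")), sp_ids)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  k <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                xml2::xml_attr(par_nodes, "id"))
  kfull <- setNames(numeric(length(.k_symbols)), .k_symbols)
  kfull[names(k)] <- k
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(nd, paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0) return(integer(0))
      sp <- match(xml2::xml_attr(refs, "species"), sp_ids)
      st <- as.integer(xml2::xml_attr(refs, "stoichiometry"))
      rep(sp, st)
    }
    cis <- xml2::xml_text(xml2::xml_find_all(nd, ".//kineticLaw//ci"))
    sym <- cis[!cis %in% sp_ids][1]
    list(id = as.integer(sub("^r", "", xml2::xml_attr(nd, "id"))),
         re = get_side("listOfReactants"), pr = get_side("listOfProducts"),
         sym = sym, scope = "imported")
  })
  S <- matrix(0L, n_sp, length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (i in r$re) S[i, j] <- S[i, j] - 1L
    for (i in r$pr) S[i, j] <- S[i, j] + 1L
  }
  rownames(S) <- sp_ids
  ra <- vapply(reactions, function(r)
    if (length(r$re) >= 1) r$re[1] else NA_integer_, 1L)
  rb <- vapply(reactions, function(r)
    if (length(r$re) >= 2) r$re[2] else NA_integer_, 1L)
  sym <- vapply(reactions, function(r) r$sym, "")
  variant <- if (n_sp >= 16) "full" else "simple"
  net <- structure(list(
    variant = variant,
    species = .species_table[seq_len(n_sp), ],
    reactions = reactions, stoichiometry = S, ra = ra, rb = rb,
    rate_symbol = sym, k_index = match(sym, .k_symbols),
    delays = rep(0, length(reactions)),
    n_species = n_sp, n_reactions = length(reactions)
  ), class = "reaction_network")
  list(network = net, k = kfull, initial_state = y0)
}
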
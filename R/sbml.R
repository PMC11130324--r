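## Structural SBML Level 3 export of the reaction network for cross-tool
## inspection. Rate laws are exported as annotations (the rate closures
## live in R/C); species, reactions, reactants/products and parameters are
## fully structural.

#' Export a reaction network to SBML Level 3
#'
#' Writes species (with initial amounts and units), reactions (reactants/
#' products from the stoichiometry, rate-law tag and a human-readable rate
#' note), and the full parameter set.
#'
#' @param network a \code{ReactionNetwork}.
#' @param file output path (.xml).
#' @return the file path, invisibly.
#' @export
exportSBML <- function(network, file) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("erbb_qsp_",
                                           network@cellLine@name))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true")
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network@species))) {
    row <- network@species[i, ]
    xml2::xml_add_child(sp, "species", id = row$name, compartment = "cell",
                        initialAmount = format(row$initial, digits = 12),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false",
                        name = paste0(row$name, " [", row$unit, "]"))
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(network@params))
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(network@params[[nm]], digits = 12),
                        constant = "true")
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in network@reactions) {
    st <- rx$stoich
    node <- xml2::xml_add_child(rxns, "reaction", id = rx$name,
                                reversible = "true", name = rx$law)
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (nm in names(st)[st < 0])
        xml2::xml_add_child(lr, "speciesReference", species = nm,
                            stoichiometry = format(abs(st[[nm]])),
                            constant = "true")
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (nm in names(st)[st > 0])
        xml2::xml_add_child(lp, "speciesReference", species = nm,
                            stoichiometry = format(st[[nm]]),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}
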
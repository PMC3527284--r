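#' Read an SBML Level 3 core model (mass-action subset)
#'
#' Supports the subset this engine simulates: species with initial amounts,
#' a single compartment giving the volume, global parameters, and reactions
#' whose kinetic law is mass action with one rate parameter (the rate
#' constant is taken to be the first `<ci>` in the kinetic-law math that
#' names a parameter; local kinetic-law parameters are promoted to model
#' parameters, prefixed with the reaction id on name clashes). Events,
#' assignment rules, function definitions, and arbitrary rate laws are out
#' of scope.
#'
#' @param path an SBML file.
#' @return an [rn_model()].
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  name <- xml2::xml_attr(model_node, "id") %||% "sbml_model"

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
    xml2::xml_attr(sp_nodes, "id"))
  if (any(is.na(species)))
    stop("SBML subset requires initialAmount on every species")

  comp <- xml2::xml_find_first(doc, ".//listOfCompartments/compartment")
  volume <- if (!inherits(comp, "xml_missing")) {
    v <- as.numeric(xml2::xml_attr(comp, "size"))
    if (is.na(v)) 1 else v
  } else 1

  par_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  parameters <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  reactions <- list()
  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    side <- function(xp) {
      refs <- xml2::xml_find_all(rx, xp)
      if (!length(refs)) return(c())
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(as.integer(st), xml2::xml_attr(refs, "species"))
    }
    # local kinetic-law parameters become model parameters
    loc <- xml2::xml_find_all(rx, ".//kineticLaw//localParameter | .//kineticLaw//parameter")
    loc_ids <- xml2::xml_attr(loc, "id")
    for (i in seq_along(loc)) {
      nm <- loc_ids[i]
      if (nm %in% names(parameters)) nm <- paste(rid, nm, sep = "_")
      parameters[nm] <- as.numeric(xml2::xml_attr(loc[i], "value"))
      loc_ids[i] <- nm
    }
    cis <- xml2::xml_text(xml2::xml_find_all(rx, ".//kineticLaw//ci"))
    cis <- trimws(cis)
    rate <- cis[cis %in% names(parameters)][1]
    if (is.na(rate) || is.null(rate))
      stop("reaction ", rid, ": no rate parameter found in kinetic law")
    reactions[[length(reactions) + 1]] <-
      list(name = rid,
           reactants = side(".//listOfReactants/speciesReference"),
           products = side(".//listOfProducts/speciesReference"),
           rate = rate)
  }
  rn_model(species = species, reactions = reactions, parameters = parameters,
           volume = volume, name = name)
}

#' Write a model as SBML Level 3 core (mass-action subset)
#'
#' The inverse of [read_sbml_model()] on the supported subset: one
#' compartment, species with initial amounts, global parameters, and
#' reactions with mass-action kinetic laws `k * reactant products`.
#'
#' @param m an [rn_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(m, path) {
  validate_rn_model(m)
  esc <- function(x) gsub("&", "&amp;", x)
  sp <- paste0(
    sprintf('      <species id="%s" compartment="c" initialAmount="%s" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
            esc(m$species$name), format_num(m$species$initial_amount)),
    collapse = "\n")
  par <- paste0(
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            esc(names(m$parameters)), format_num(unname(m$parameters))),
    collapse = "\n")
  rxs <- vapply(seq_along(m$reactions), function(i) {
    r <- m$reactions[[i]]
    rid <- r$name %||% paste0("r", i)
    refs <- function(st, tag) {
      if (!length(st)) return("")
      inner <- paste0(sprintf('          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                              names(st), as.integer(st)), collapse = "\n")
      sprintf("        <listOf%ss>\n%s\n        </listOf%ss>", tag, inner, tag)
    }
    terms <- c(r$rate, rep(names(r$reactants), r$reactants))
    math <- paste0("            <apply><times/>",
                   paste0("<ci> ", terms, " </ci>", collapse = ""),
                   "</apply>")
    if (length(terms) == 1)
      math <- paste0("            <ci> ", terms, " </ci>")
    paste0('      <reaction id="', rid, '" reversible="false">\n',
           paste(Filter(nzchar, c(refs(r$reactants, "Reactant"),
                                  refs(r$products, "Product"))), collapse = "\n"),
           '\n        <kineticLaw>\n          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
           math,
           '\n          </math>\n        </kineticLaw>\n      </reaction>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '  <model id="', esc(m$name), '">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="c" size="', format_num(m$volume), '" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', sp, '\n    </listOfSpecies>\n',
    '    <listOfParameters>\n', par, '\n    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rxs, collapse = "\n"), '\n    </listOfReactions>\n',
    '  </model>\n</sbml>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}
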
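## SBML Level 3 (+ flux-bound annotations in the fbc-v2 style) reader and
## writer for the subset of constructs this package emits: compartments,
## species, reactions with stoichiometries, per-reaction flux-bound
## parameters and a biomass objective.  Community metadata that SBML does not
## carry (member list, biomass ids, recycling block) travels in a JSON
## manifest next to the file.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x) gsub(":", "__", x)
sbml_unid <- function(x) gsub("__", ":", x)
num17 <- function(x) sprintf("%.17g", x)

write_sbml_file <- function(path, model_id, mets, met_comp, rxns, S, lb, ub,
                            objective_rxns) {
  comps <- unique(met_comp)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", SBML_CORE_NS, "\" xmlns:fbc=\"", SBML_FBC_NS,
           "\" level=\"3\" version=\"1\" fbc:required=\"false\">"),
    paste0("  <model id=\"", sbml_id(model_id), "\" fbc:strict=\"true\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"", sbml_id(comps),
           "\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    paste0("      <species id=\"M_", sbml_id(mets), "\" compartment=\"",
           sbml_id(met_comp), "\" hasOnlySubstanceUnits=\"false\"",
           " boundaryCondition=\"false\" constant=\"false\"/>"),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    paste0("      <parameter id=\"P_lb_", sbml_id(rxns), "\" value=\"",
           num17(lb), "\" constant=\"true\"/>"),
    paste0("      <parameter id=\"P_ub_", sbml_id(rxns), "\" value=\"",
           num17(ub), "\" constant=\"true\"/>"),
    "    </listOfParameters>",
    "    <listOfReactions>")
  for (j in seq_along(rxns)) {
    rid <- sbml_id(rxns[j])
    coef <- S[, j]
    sub <- which(coef < 0); prod <- which(coef > 0)
    lines <- c(lines, paste0(
      "      <reaction id=\"R_", rid, "\" reversible=\"",
      tolower(lb[j] < 0), "\" fast=\"false\" fbc:lowerFluxBound=\"P_lb_",
      rid, "\" fbc:upperFluxBound=\"P_ub_", rid, "\">"))
    if (length(sub)) {
      lines <- c(lines, "        <listOfReactants>",
                 paste0("          <speciesReference species=\"M_",
                        sbml_id(mets[sub]), "\" stoichiometry=\"",
                        num17(-coef[sub]), "\" constant=\"true\"/>"),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 paste0("          <speciesReference species=\"M_",
                        sbml_id(mets[prod]), "\" stoichiometry=\"",
                        num17(coef[prod]), "\" constant=\"true\"/>"),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(objective_rxns)) {
    lines <- c(lines,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>",
      paste0("          <fbc:fluxObjective fbc:reaction=\"R_",
             sbml_id(objective_rxns), "\" fbc:coefficient=\"1\"/>"),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}

parse_sbml_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("ill-formed SBML in ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML parse error: no species found (listOfSpecies)")
  mets <- sbml_unid(sub("^M_", "", xml2::xml_attr(sp, "id")))
  met_comp <- sbml_unid(xml2::xml_attr(sp, "compartment"))
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  rn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rn)) stop("SBML parse error: no reactions found (listOfReactions)")
  rxns <- sbml_unid(sub("^R_", "", xml2::xml_attr(rn, "id")))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  lb <- ub <- stats::setNames(numeric(length(rxns)), rxns)
  for (j in seq_along(rn)) {
    node <- rn[[j]]
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !lbp %in% names(pvals) ||
        !ubp %in% names(pvals))
      stop("SBML parse error: reaction '", rxns[j],
           "' lacks resolvable flux-bound parameters")
    lb[j] <- pvals[[lbp]]; ub[j] <- pvals[[ubp]]
    for (sr in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      m <- sbml_unid(sub("^M_", "", xml2::xml_attr(sr, "species")))
      S[m, j] <- S[m, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      m <- sbml_unid(sub("^M_", "", xml2::xml_attr(sr, "species")))
      S[m, j] <- S[m, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
  }
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objective <- sbml_unid(sub("^R_", "", xml2::xml_attr(fo, "reaction")))
  list(model_id = sbml_unid(xml2::xml_attr(
         xml2::xml_find_first(doc, ".//model"), "id")),
       mets = mets, met_comp = stats::setNames(met_comp, mets),
       rxns = rxns, S = S, lb = lb, ub = ub, objective = objective)
}

manifest_path <- function(path) paste0(path, ".json")

#' Load a single-organism model from SBML
#'
#' Reads an SBML Level 3 file with flux-bound annotations and returns a
#' validated \code{\link{organism_model}}.  The biomass reaction is taken
#' from the active flux objective unless given explicitly.
#'
#' @param path SBML file path.
#' @param biomass_id biomass reaction id (overrides the file's objective).
#' @param organism_id organism id (defaults to the SBML model id).
#' @param extracellular extracellular compartment id (default "e").
#' @return an \code{\link{organism_model}}.
#' @export
load_model <- function(path, biomass_id = NULL, organism_id = NULL,
                       extracellular = "e") {
  p <- parse_sbml_file(path)
  if (is.null(biomass_id)) {
    if (length(p$objective) == 1L) biomass_id <- p$objective
    else stop("no unambiguous biomass objective in ", path,
              "; supply biomass_id explicitly")
  }
  organism_model(organism_id %||% p$model_id, p$S, p$lb, p$ub, p$met_comp,
                 biomass_id, extracellular = extracellular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model to SBML (+ JSON manifest for communities)
#'
#' Organism models round-trip through \code{\link{load_model}}; community
#' models additionally write a JSON manifest (\code{<path>.json}) holding
#' member ids, biomass reaction ids and the recycling block, and round-trip
#' through \code{\link{load_community}}.
#'
#' @param model an \code{organism_model} or \code{community_model}.
#' @param path output SBML path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "organism_model")) {
    write_sbml_file(path, model$organism_id, rownames(model$S),
                    unname(model$met_compartment), colnames(model$S),
                    model$S, unname(model$lb), unname(model$ub),
                    model$biomass_id)
  } else if (inherits(model, "community_model")) {
    write_sbml_file(path, paste(model$members, collapse = "_"),
                    rownames(model$S), unname(model$met_compartment),
                    colnames(model$S), model$S, unname(model$lb),
                    unname(model$ub), unname(model$biomass_ids))
    jsonlite::write_json(
      list(type = "community", members = model$members,
           biomass_ids = as.list(model$biomass_ids),
           recycling = model$recycling),
      manifest_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("write_model handles organism_model and community_model")
  invisible(path)
}

#' Load a community model from SBML + manifest
#'
#' @param path SBML file path written by \code{\link{write_model}}; the
#'   manifest \code{<path>.json} must exist.
#' @return a \code{community_model}.
#' @export
load_community <- function(path) {
  p <- parse_sbml_file(path)
  mpath <- manifest_path(path)
  if (!file.exists(mpath))
    stop("community manifest not found: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  members <- man$members
  rxn_organism <- rep(NA_character_, length(p$rxns))
  rxn_original <- p$rxns
  for (org in members[order(nchar(members))]) {   # longest prefix wins
    pre <- paste0(org, "_")
    hit <- startsWith(p$rxns, pre)
    rxn_organism[hit] <- org
    rxn_original[hit] <- substring(p$rxns[hit], nchar(pre) + 1L)
  }
  pool_mets <- p$mets[p$met_comp == "pool" & !p$mets %in%
                        c("Biomass_community", "Biomass_degraded",
                          "Biomass_net")]
  exch <- p$rxns[is.na(rxn_organism) & startsWith(p$rxns, "EX_")]
  recycling <- man$recycling
  if (!is.null(recycling) && length(recycling) == 0L) recycling <- NULL
  structure(list(
    members = members, S = p$S, lb = p$lb, ub = p$ub,
    rxn_organism = stats::setNames(rxn_organism, p$rxns),
    rxn_original = stats::setNames(rxn_original, p$rxns),
    biomass_ids = stats::setNames(unlist(man$biomass_ids), names(man$biomass_ids)),
    met_compartment = p$met_comp,
    pool_mets = pool_mets,
    exchange_ids = exch,
    recycling = recycling
  ), class = "community_model")
}
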
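# Minimal SBML reader: stoichiometry, reversibility and flux bounds only.

#' Read a metabolic model from SBML
#'
#' Supports the subset of SBML Level 2/3 needed for constraint-based flux
#' analysis: `listOfSpecies` (species with `boundaryCondition="true"` are
#' dropped from the stoichiometric matrix), `listOfReactions` with
#' reactant/product stoichiometries, reversibility flags, and flux bounds
#' taken from either Level-2 `kineticLaw` parameters named
#' `LOWER_BOUND`/`UPPER_BOUND` or Level-3 `fbc` bound attributes resolved
#' through the global parameter list. Reactions without bounds get
#' `default_bounds` (reversible) or `c(0, default_bounds[2])` (irreversible).
#'
#' @param path SBML file path.
#' @param biomass_id optional biomass reaction id; when `NULL`, the `fbc`
#'   active objective is used if present, else the first reaction id matching
#'   `"biomass"` case-insensitively.
#' @param default_bounds length-2 numeric, conventional defaults `c(-1000, 1000)`.
#' @return an [fmb_model]; reaction order follows the file.
#' @export
read_sbml <- function(path, biomass_id = NULL, default_bounds = c(-1000, 1000)) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_fmb("malformed SBML in '%s': %s",
                                               path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) stop_fmb("malformed SBML: no <model> element in '%s'", path)

  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  if (!length(rx_nodes)) stop_fmb("malformed SBML: no reactions in '%s'", path)
  n <- length(rx_nodes)
  rxns <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rxns)) stop_fmb("duplicate reaction id in SBML '%s'", path)
  rev <- !(xml2::xml_attr(rx_nodes, "reversible") %in% "false")
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxns))
  lower <- numeric(n); upper <- numeric(n); exch <- logical(n)

  species_refs <- function(node, which) {
    refs <- xml2::xml_find_all(node, sprintf("./%s/speciesReference", which))
    sp <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    stats::setNames(st, sp)
  }
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    reac <- species_refs(node, "listOfReactants")
    prod <- species_refs(node, "listOfProducts")
    internal_r <- intersect(names(reac), mets)
    internal_p <- intersect(names(prod), mets)
    for (met in internal_r) S[met, j] <- S[met, j] - reac[met]
    for (met in internal_p) S[met, j] <- S[met, j] + prod[met]
    exch[j] <- length(internal_r) == 0 || length(internal_p) == 0

    lb <- ub <- NA_real_
    kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if ("LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      if ("UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(pval)) lb <- pval[[lbref]]
    if (!is.na(ubref) && ubref %in% names(pval)) ub <- pval[[ubref]]
    if (is.na(lb)) lb <- if (rev[j]) default_bounds[1] else 0
    if (is.na(ub)) ub <- default_bounds[2]
    lower[j] <- lb; upper[j] <- ub
  }
  # a negative lower bound implies reversibility whatever the flag says
  rev <- rev | lower < 0

  if (is.null(biomass_id)) {
    obj <- xml2::xml_find_first(model_node, ".//listOfObjectives//fluxObjective")
    if (!is.na(obj)) biomass_id <- xml2::xml_attr(obj, "reaction")
    if (is.null(biomass_id) || is.na(biomass_id)) {
      hit <- grep("biomass", rxns, ignore.case = TRUE)
      biomass_id <- if (length(hit)) rxns[hit[1]] else NA_character_
    }
  }
  fmb_model(S, lower, upper, rev, biomass_id = biomass_id, exchange = exch)
}
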
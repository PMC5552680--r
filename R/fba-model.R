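#' Construct a validated stoichiometric metabolic model
#'
#' Holds the stoichiometric matrix S (metabolites x reactions), per-reaction
#' flux bounds, exchange flags, the identifier of the ATP species, and the
#' set of inorganic metabolites whose exchanges stay open during ATP-yield
#' calculations.  Exchange reactions transport a single metabolite across
#' the system boundary and are written `met -> (nothing)`, so a positive
#' exchange flux is secretion and a negative one uptake.
#'
#' @param metabolites character vector of metabolite identifiers.
#' @param reactions named list; each element a list with `stoich` (named
#'   numeric: metabolite -> coefficient), `lb`, `ub`, and logical `exchange`.
#' @param atp identifier of the ATP species.
#' @param inorganic metabolite identifiers treated as freely exchangeable
#'   (oxygen, CO2, ...) when organic uptakes are closed.
#' @return object of class `metabolic_model` with fields `mets`, `rxns`,
#'   `S`, `lb`, `ub`, `exchange`, `atp`, `inorganic`.
#' @export
metabolic_model <- function(metabolites, reactions, atp,
                            inorganic = character(0)) {
  mets <- as.character(metabolites)
  if (anyDuplicated(mets)) stop("duplicate metabolite identifiers")
  rxn_ids <- names(reactions)
  if (is.null(rxn_ids) || anyDuplicated(rxn_ids) || any(!nzchar(rxn_ids)))
    stop("reactions must be a uniquely named list")
  S <- matrix(0, length(mets), length(reactions),
              dimnames = list(mets, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(reactions)), rxn_ids)
  exch <- stats::setNames(logical(length(reactions)), rxn_ids)
  for (id in rxn_ids) {
    r <- reactions[[id]]
    st <- r$stoich
    unknown <- setdiff(names(st), mets)
    if (length(unknown))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   id, paste(unknown, collapse = ", ")))
    if (!is.numeric(r$lb) || !is.numeric(r$ub) || r$lb > r$ub)
      stop(sprintf("reaction '%s': need numeric bounds with lb <= ub", id))
    S[names(st), id] <- as.numeric(st)
    lb[id] <- r$lb; ub[id] <- r$ub
    exch[id] <- isTRUE(r$exchange)
    if (exch[id] && sum(S[, id] != 0) != 1)
      stop(sprintf("exchange reaction '%s' must touch exactly one metabolite",
                   id))
  }
  if (!atp %in% mets)
    stop("ATP species '", atp, "' not among the metabolites")
  bad <- setdiff(inorganic, mets)
  if (length(bad))
    stop("unknown inorganic metabolite(s): ", paste(bad, collapse = ", "))
  structure(list(mets = mets, rxns = rxn_ids, S = S, lb = lb, ub = ub,
                 exchange = exch, atp = atp,
                 inorganic = as.character(inorganic)),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d metabolites, %d reactions (%d exchanges)\n",
              length(x$mets), length(x$rxns), sum(x$exchange)))
  cat(sprintf("  ATP species: %s\n", x$atp))
  invisible(x)
}

#' Map metabolites to their exchange reactions
#'
#' @param model a [metabolic_model()].
#' @return named character vector metabolite -> exchange reaction id.
#' @export
exchange_map <- function(model) {
  ex <- model$rxns[model$exchange]
  mets <- vapply(ex, function(id) model$mets[which(model$S[, id] != 0)],
                 character(1))
  stats::setNames(ex, mets)
}

#' Load a metabolic model from JSON
#'
#' Dialect: `{"metabolites": [...], "reactions": [{"id", "stoich":
#' {met: coeff}, "lb", "ub", "exchange"}], "atp": "...",
#' "inorganic": [...]}`.  The `inorganic` field is optional.
#'
#' @param path JSON file path.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions) || is.null(j$atp))
    stop("model JSON needs 'metabolites', 'reactions' and 'atp'")
  rxns <- list()
  for (r in j$reactions) {
    if (is.null(r$id)) stop("every reaction needs an 'id'")
    rxns[[r$id]] <- list(stoich = unlist(r$stoich),
                         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
                         exchange = isTRUE(r$exchange))
  }
  metabolic_model(unlist(j$metabolites), rxns, atp = j$atp,
                  inorganic = as.character(unlist(j$inorganic)))
}

#' Write a metabolic model to JSON
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  rx <- lapply(model$rxns, function(id) {
    st <- model$S[, id]
    st <- st[st != 0]
    list(id = id, stoich = as.list(st), lb = model$lb[[id]],
         ub = model$ub[[id]], exchange = model$exchange[[id]])
  })
  jsonlite::write_json(list(metabolites = model$mets, reactions = rx,
                            atp = model$atp, inorganic = model$inorganic),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a model to SBML Level 3 (fbc bounds)
#'
#' Minimal SBML serialisation: species, reactions with reactant/product
#' stoichiometries, and flux bounds as fbc parameters.  The ATP tag and the
#' inorganic list have no SBML slot and must be re-supplied on import.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "model")
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$mets)
    xml2::xml_add_child(los, "species", id = m, compartment = "c",
                        boundaryCondition = "false")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (id in model$rxns) {
    lbid <- paste0(id, "_lb"); ubid <- paste0(id, "_ub")
    xml2::xml_add_child(lop, "parameter", id = lbid,
                        value = format(model$lb[[id]], digits = 15),
                        constant = "true")
    xml2::xml_add_child(lop, "parameter", id = ubid,
                        value = format(model$ub[[id]], digits = 15),
                        constant = "true")
    rx <- xml2::xml_add_child(lor, "reaction", id = id,
                              reversible = tolower(model$lb[[id]] < 0),
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    st <- model$S[, id]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lr, "speciesReference", species = m,
                            stoichiometry = format(-reac[[m]], digits = 15))
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lp, "speciesReference", species = m,
                            stoichiometry = format(prod[[m]], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML Level 3 (fbc bounds)
#'
#' Counterpart of [write_model_sbml()].  Exchange reactions are recognised
#' by the conventional `EX_` identifier prefix together with touching
#' exactly one species (a bare single-species demand such as an ATP
#' maintenance reaction is not an exchange).
#'
#' @param path SBML file.
#' @param atp identifier of the ATP species (not representable in SBML).
#' @param inorganic inorganic metabolite identifiers (idem).
#' @return a [metabolic_model()].
#' @export
read_model_sbml <- function(path, atp, inorganic = character(0)) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mets <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"),
                         "id")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rxns <- list()
  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    id <- xml2::xml_attr(rx, "id")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference"))
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference"))
      st[xml2::xml_attr(sr, "species")] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    lb <- pval[[xml2::xml_attr(rx, "lowerFluxBound")]]
    ub <- pval[[xml2::xml_attr(rx, "upperFluxBound")]]
    rxns[[id]] <- list(stoich = st, lb = lb, ub = ub,
                       exchange = sum(st != 0) == 1 && startsWith(id, "EX_"))
  }
  metabolic_model(mets, rxns, atp = atp, inorganic = inorganic)
}
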
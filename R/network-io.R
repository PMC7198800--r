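# Network and media I/O: a small documented JSON dialect plus an optional
# SBML Level-3 FBC mapping onto the same fields.

.net_to_list <- function(net) {
  list(
    id = net$id,
    metabolites = unname(lapply(net$metabolites, function(m)
      list(id = m$id, name = m$name, compartment = m$compartment))),
    reactions = unname(lapply(net$reactions, function(r)
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           is_exchange = r$is_exchange, is_biomass = r$is_biomass)))
  )
}

.list_to_parts <- function(x) {
  mets <- lapply(x$metabolites, function(m)
    metabolite(m$id, m$name %||% m$id, m$compartment))
  rxns <- lapply(x$reactions, function(r) {
    st <- vapply(r$stoichiometry, as.numeric, numeric(1))
    reaction(r$id, st,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             is_exchange = isTRUE(r$is_exchange),
             is_biomass = isTRUE(r$is_biomass))
  })
  list(metabolites = mets, reactions = rxns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network or universal database to JSON
#'
#' The dialect stores `id`, a `metabolites` array (`id`, `name`,
#' `compartment`) and a `reactions` array (`id`, `stoichiometry` map,
#' `lower_bound`, `upper_bound`, `is_exchange`, `is_biomass`).
#'
#' @param net A `metabolic_network` or `universal_db`.
#' @param path Output file path.
#' @export
write_network_json <- function(net, path) {
  x <- .net_to_list(net)
  x$type <- if (inherits(net, "universal_db")) "universal_db" else
    "metabolic_network"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network or universal database from JSON
#' @param path File written by [write_network_json()].
#' @return A `metabolic_network` or `universal_db`.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path)
  p <- .list_to_parts(x)
  if (identical(x$type, "universal_db"))
    universal_db(x$id, p$metabolites, p$reactions)
  else
    metabolic_network(x$id, p$metabolites, p$reactions)
}

#' Read / write a media panel
#'
#' Tab-separated long format with columns `condition_id`, `exchange_id`,
#' `max_uptake`, `is_nitrogen_source`.
#'
#' @param panel Named list of [medium_condition()] objects.
#' @param path TSV file path.
#' @return `read_media_tsv` returns a named list of media conditions.
#' @export
write_media_tsv <- function(panel, path) {
  rows <- do.call(rbind, lapply(panel, function(m)
    data.frame(condition_id = m$id,
               exchange_id = names(m$uptake_bounds),
               max_uptake = unname(m$uptake_bounds),
               is_nitrogen_source =
                 names(m$uptake_bounds) == m$nitrogen_source_id)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_media_tsv
#' @export
read_media_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$condition_id), function(d) {
    ub <- stats::setNames(d$max_uptake, d$exchange_id)
    medium_condition(d$condition_id[1L], ub,
                     d$exchange_id[d$is_nitrogen_source][1L])
  })
  out[unique(df$condition_id)]
}

# ---- SBML Level 3 + FBC v2 ------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Export a network to SBML Level 3 (FBC)
#'
#' Minimal mapping of the package's network fields onto SBML L3v1 with the
#' FBC v2 flux-bound and objective annotations; intended for interchange
#' with constraint-based modeling tools.
#'
#' @param net A `metabolic_network`.
#' @param path Output file path.
#' @export
write_network_sbml <- function(net, path) {
  validate_network(net)
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS,
                            "xmlns:fbc" = .FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = .sbml_id(net$id),
                               "fbc:strict" = "false")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in unique(vapply(net$metabolites, `[[`, character(1),
                            "compartment")))
    xml2::xml_add_child(comps, "compartment", id = .sbml_id(cmp),
                        constant = "true")
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in net$metabolites)
    xml2::xml_add_child(sp, "species", id = .sbml_id(m$id), name = m$name,
                        compartment = .sbml_id(m$compartment),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  rx <- xml2::xml_add_child(model, "listOfReactions")
  for (r in net$reactions) {
    lbid <- paste0("lb_", .sbml_id(r$id))
    ubid <- paste0("ub_", .sbml_id(r$id))
    xml2::xml_add_child(pars, "parameter", id = lbid,
                        value = format(r$lower_bound), constant = "true")
    xml2::xml_add_child(pars, "parameter", id = ubid,
                        value = format(r$upper_bound), constant = "true")
    rn <- xml2::xml_add_child(rx, "reaction", id = .sbml_id(r$id),
                              reversible = if (r$lower_bound < 0) "true"
                              else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    subs <- r$stoichiometry[r$stoichiometry < 0]
    prods <- r$stoichiometry[r$stoichiometry > 0]
    if (length(subs)) {
      lo <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(subs))
        xml2::xml_add_child(lo, "speciesReference",
                            species = .sbml_id(names(subs)[i]),
                            stoichiometry = format(abs(subs[[i]])),
                            constant = "true")
    }
    if (length(prods)) {
      lo <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prods))
        xml2::xml_add_child(lo, "speciesReference",
                            species = .sbml_id(names(prods)[i]),
                            stoichiometry = format(prods[[i]]),
                            constant = "true")
    }
  }
  objs <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = .sbml_id(biomass_id(net)),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Import a network from SBML Level 3 (FBC)
#'
#' Reads the subset of SBML written by [write_network_sbml()]: species,
#' reactions with FBC flux bounds, and the active maximization objective
#' (taken as the biomass reaction). Exchange reactions are recognized as
#' single-species reactions on extracellular metabolites.
#'
#' @param path SBML file path.
#' @param extracellular Compartment id treated as extracellular.
#' @return A `metabolic_network`.
#' @export
read_network_sbml <- function(path, extracellular = "e") {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  pars <- xml2::xml_find_all(model, ".//s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  mets <- lapply(xml2::xml_find_all(model, ".//s:species", ns), function(nd)
    metabolite(xml2::xml_attr(nd, "id"),
               xml2::xml_attr(nd, "name") %||% xml2::xml_attr(nd, "id"),
               xml2::xml_attr(nd, "compartment")))
  bio <- xml2::xml_attr(
    xml2::xml_find_first(model, ".//fbc:fluxObjective", ns), "reaction")
  rxns <- lapply(xml2::xml_find_all(model, ".//s:reaction", ns),
                 function(nd) {
    id <- xml2::xml_attr(nd, "id")
    refs <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference",
                               ns)
    st <- stats::setNames(-as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                          xml2::xml_attr(refs, "species"))
    refs <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference",
                               ns)
    st <- c(st, stats::setNames(
      as.numeric(xml2::xml_attr(refs, "stoichiometry")),
      xml2::xml_attr(refs, "species")))
    lb <- pval[[xml2::xml_attr(nd, "lowerFluxBound")]] %||% -1000
    ub <- pval[[xml2::xml_attr(nd, "upperFluxBound")]] %||% 1000
    reaction(id, st, lb, ub, is_exchange = FALSE,
             is_biomass = identical(id, bio))
  })
  met_comp <- stats::setNames(
    vapply(mets, `[[`, character(1), "compartment"),
    vapply(mets, `[[`, character(1), "id"))
  rxns <- lapply(rxns, function(r) {
    if (length(r$stoichiometry) == 1L &&
        identical(met_comp[[names(r$stoichiometry)]], extracellular) &&
        !r$is_biomass)
      r$is_exchange <- TRUE
    r
  })
  metabolic_network(xml2::xml_attr(model, "id"), mets, rxns)
}
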
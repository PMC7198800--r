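#' Create a metabolite
#'
#' @param id Unique metabolite identifier.
#' @param name Human-readable name (defaults to `id`).
#' @param compartment Compartment label, e.g. `"c"` (cytosol) or `"e"`
#'   (extracellular). Must be non-empty.
#' @return A `metabolite` object.
#' @export
metabolite <- function(id, name = id, compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(compartment), length(compartment) == 1L,
            nzchar(compartment))
  structure(list(id = id, name = name, compartment = compartment),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometry is a named numeric vector of signed coefficients
#' (negative = consumed, positive = produced). Fluxes are in arbitrary
#' toy units of mmol/gDW/h; bounds must satisfy `lower_bound <=
#' upper_bound`. Exchange reactions must touch exactly one metabolite
#' (the extracellular boundary species); by convention negative flux
#' through an exchange is uptake and positive flux is secretion.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds.
#' @param is_exchange Logical flag for boundary exchange reactions.
#' @param is_biomass Logical flag for the biomass objective reaction.
#' @return A `reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, is_exchange = FALSE,
                     is_biomass = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || length(stoichiometry) == 0L ||
      is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named ",
         "numeric vector")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  if (!is.finite(lower_bound) || !is.finite(upper_bound) ||
      lower_bound > upper_bound)
    stop("reaction '", id, "': requires finite lower_bound <= upper_bound")
  if (isTRUE(is_exchange) && length(stoichiometry) != 1L)
    stop("exchange reaction '", id, "' must touch exactly one metabolite")
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 is_exchange = isTRUE(is_exchange),
                 is_biomass = isTRUE(is_biomass)),
            class = "reaction")
}

#' Create a metabolic network
#'
#' A validated container of metabolites and stoichiometric reactions with
#' exactly one biomass reaction; the unit on which flux balance analysis
#' and gapfilling operate.
#'
#' @param id Network identifier.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects, exactly one of which has
#'   `is_biomass = TRUE`.
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(id, metabolites, reactions) {
  net <- structure(list(id = id,
                        metabolites = .index_by_id(metabolites, "metabolite"),
                        reactions = .index_by_id(reactions, "reaction")),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Create a universal reaction database
#'
#' Same shape as a [metabolic_network()] but without a biomass reaction;
#' the superset of candidate reactions drawn on during gapfilling.
#'
#' @inheritParams metabolic_network
#' @return A `universal_db` object.
#' @export
universal_db <- function(id, metabolites, reactions) {
  db <- structure(list(id = id,
                       metabolites = .index_by_id(metabolites, "metabolite"),
                       reactions = .index_by_id(reactions, "reaction")),
                  class = "universal_db")
  if (any(vapply(db$reactions, `[[`, logical(1), "is_biomass")))
    stop("a universal database must not contain a biomass reaction")
  .check_metabolite_refs(db)
  db
}

#' Create a medium condition
#'
#' Encodes one growth condition: which exchange reactions are open to
#' uptake and at what maximal rate, and which exchange supplies the
#' nitrogen source. Exchanges not listed are closed to uptake but remain
#' open to secretion.
#'
#' @param id Condition identifier (usually the nitrogen substrate name).
#' @param uptake_bounds Named numeric vector, exchange reaction id ->
#'   maximal uptake flux (must be >= 0).
#' @param nitrogen_source_id Exchange reaction id of the nitrogen source.
#' @return A `medium_condition` object.
#' @export
medium_condition <- function(id, uptake_bounds, nitrogen_source_id) {
  stopifnot(is.numeric(uptake_bounds), !is.null(names(uptake_bounds)))
  if (any(uptake_bounds < 0)) stop("uptake bounds must be >= 0")
  if (!nitrogen_source_id %in% names(uptake_bounds))
    stop("nitrogen_source_id must appear in uptake_bounds")
  structure(list(id = id, uptake_bounds = uptake_bounds,
                 nitrogen_source_id = nitrogen_source_id),
            class = "medium_condition")
}

.index_by_id <- function(x, what) {
  stopifnot(is.list(x), length(x) > 0L)
  ids <- vapply(x, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicated ", what, " ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(x) <- ids
  x
}

.check_metabolite_refs <- function(net) {
  met_ids <- names(net$metabolites)
  for (r in net$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  invisible(net)
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique ids, exactly one biomass
#' reaction, every referenced metabolite present, and exchange reactions
#' touching a single extracellular metabolite.
#'
#' @param net A `metabolic_network`.
#' @return The network, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  if (!inherits(net, "metabolic_network")) stop("not a metabolic_network")
  .check_metabolite_refs(net)
  bm <- vapply(net$reactions, `[[`, logical(1), "is_biomass")
  if (sum(bm) != 1L)
    stop("network '", net$id, "' must contain exactly one biomass ",
         "reaction (found ", sum(bm), ")")
  for (r in net$reactions) {
    if (r$is_exchange) {
      met <- net$metabolites[[names(r$stoichiometry)]]
      if (!identical(met$compartment, "e"))
        stop("exchange reaction '", r$id,
             "' must touch an extracellular ('e') metabolite")
    }
  }
  invisible(net)
}

#' @export
biomass_id <- function(net) {
  names(net$reactions)[vapply(net$reactions, `[[`, logical(1), "is_biomass")]
}

#' Add or replace reactions in a network
#' @param net A `metabolic_network`.
#' @param reactions List of [reaction()] objects; metabolites they
#'   reference but the network lacks are pulled from `from`.
#' @param from Optional `universal_db` supplying missing metabolites.
#' @return The extended network.
#' @export
add_reactions <- function(net, reactions, from = NULL) {
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), names(net$metabolites))
    if (length(missing)) {
      if (is.null(from) || !all(missing %in% names(from$metabolites)))
        stop("cannot resolve metabolite(s) ", paste(missing, collapse = ", "),
             " for reaction '", r$id, "'")
      net$metabolites <- c(net$metabolites, from$metabolites[missing])
    }
    net$reactions[[r$id]] <- r
  }
  validate_network(net)
  net
}

#' Remove reactions from a network
#' @param net A `metabolic_network`.
#' @param ids Reaction ids to drop (biomass may not be removed).
#' @return The reduced network.
#' @export
remove_reactions <- function(net, ids) {
  if (biomass_id(net) %in% ids) stop("cannot remove the biomass reaction")
  net$reactions <- net$reactions[setdiff(names(net$reactions), ids)]
  validate_network(net)
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  nex <- sum(vapply(x$reactions, `[[`, logical(1), "is_exchange"))
  cat("<metabolic_network> ", x$id, ": ",
      length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", nex, " exchanges), biomass = ",
      biomass_id(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.universal_db <- function(x, ...) {
  cat("<universal_db> ", x$id, ": ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' @export
print.medium_condition <- function(x, ...) {
  cat("<medium_condition> ", x$id, ": N source ", x$nitrogen_source_id,
      "; ", length(x$uptake_bounds), " open uptake exchange(s)\n", sep = "")
  invisible(x)
}

#' Check that a draft network is covered by a universal database
#'
#' Every non-biomass, non-exchange draft reaction must exist in the
#' database (draft-specific exchanges are allowed).
#'
#' @param draft A `metabolic_network`.
#' @param db A `universal_db`.
#' @return TRUE invisibly, or an error listing uncovered reactions.
#' @export
check_db_coverage <- function(draft, db) {
  ids <- names(draft$reactions)
  core <- ids[!vapply(draft$reactions, function(r)
    r$is_biomass || r$is_exchange, logical(1))]
  missing <- setdiff(core, names(db$reactions))
  if (length(missing))
    stop("draft reactions absent from the universal database: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
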
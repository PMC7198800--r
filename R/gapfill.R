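# Positive and negative gapfilling against a universal reaction database.
#
# Positive gapfilling adds the smallest set of database reactions that
# lets a draft grow on a medium. When the candidate set is small
# (<= exact_limit) an iterative-deepening exhaustive search certifies
# minimum cardinality, with ties broken lexicographically on the sorted
# id tuple. Larger instances use the flux-support + greedy-pruning
# heuristic: the support of an optimum with all candidates open is
# trimmed until irreducible. The heuristic result is minimal (no proper
# subset works) but not certified minimum-cardinality; `certified`
# reports which route produced the answer.

#' Positive gapfilling
#'
#' @param draft A `metabolic_network` that (typically) fails to grow on
#'   `medium`.
#' @param db A [universal_db()] of candidate reactions.
#' @param medium A [medium_condition()].
#' @param epsilon Growth threshold passed to [predicts_growth()].
#' @param exact_limit Maximum candidate-set size for the certified
#'   exhaustive search (default 12).
#' @return A list with `network` (gapfilled), `added` (character vector,
#'   sorted), and `certified` (logical: minimum cardinality certified).
#'   If the draft already grows it is returned unchanged with
#'   `added = character(0)`. If no database subset enables growth an
#'   error of class `nitrofill_ungapfillable` is raised carrying the
#'   condition id.
#' @export
gapfill_positive <- function(draft, db, medium, epsilon = 1e-3,
                             exact_limit = 12L) {
  validate_network(draft)
  if (predicts_growth(draft, medium, epsilon))
    return(list(network = draft, added = character(0), certified = TRUE))

  cand_ids <- sort(setdiff(names(db$reactions), names(draft$reactions)))
  merged <- add_reactions(draft, db$reactions[cand_ids], from = db)
  ctx <- .lp_context(merged$reactions, names(merged$metabolites))

  if (!.ctx_grows(ctx, medium, epsilon))
    stop(structure(class = c("nitrofill_ungapfillable", "error",
                             "condition"),
                   list(message = paste0(
                     "no database subset enables growth on condition '",
                     medium$id, "'"), call = sys.call(-1),
                     condition_id = medium$id)))

  grows_with <- function(open) {
    .ctx_grows(ctx, medium, epsilon, closed = setdiff(cand_ids, open))
  }

  added <- NULL
  certified <- FALSE
  if (length(cand_ids) <= exact_limit) {
    for (k in seq_along(cand_ids)) {
      combos <- utils::combn(cand_ids, k, simplify = FALSE)
      for (s in combos) {        # combn is lexicographic on sorted ids
        if (grows_with(s)) { added <- s; break }
      }
      if (!is.null(added)) break
    }
    certified <- TRUE
  } else {
    ## heuristic: support of an all-open optimum, then greedy pruning
    sol <- .ctx_fba(ctx, medium)
    fl <- stats::setNames(sol$x, ctx$rxn_ids)
    support <- sort(cand_ids[abs(fl[cand_ids]) > .FLUX_TOL])
    if (!grows_with(support)) support <- cand_ids   # safety net
    added <- support
    for (id in support) {
      trial <- setdiff(added, id)
      if (grows_with(trial)) added <- trial
    }
  }
  net <- add_reactions(draft, db$reactions[added], from = db)
  list(network = net, added = sort(added), certified = certified)
}

#' Negative gapfilling (trimming)
#'
#' Tries to abolish growth on a non-growth condition by removing
#' previously added reactions, without breaking any satisfied positive
#' condition. Candidate removals are the removable reactions carrying
#' flux on the negative condition, tried in a seeded random order; a
#' removal is kept only if every satisfied positive still grows. If the
#' negative condition cannot be silenced the network is returned
#' unchanged with `resolved = FALSE` (a flagged result, not an error).
#'
#' @param network A `metabolic_network`.
#' @param negative_medium The condition that should not support growth.
#' @param satisfied_positives List of media the network must keep growing
#'   on.
#' @param removable_ids Reactions eligible for removal (by design, the
#'   previously gapfilled additions; draft-original reactions are never
#'   removed). Defaults to none, which makes the call a pure check.
#' @param epsilon Growth threshold.
#' @param seed Integer seed ordering the candidate removals.
#' @return List with `network`, `removed` (character), `resolved`
#'   (logical: negative condition is non-growing on return).
#' @export
gapfill_negative <- function(network, negative_medium,
                             satisfied_positives = list(),
                             removable_ids = character(0),
                             epsilon = 1e-3, seed = 1L) {
  validate_network(network)
  for (p in satisfied_positives)
    if (!predicts_growth(network, p, epsilon))
      stop("satisfied positive '", p$id, "' does not grow on entry")

  ctx <- .lp_context(network$reactions, names(network$metabolites))
  all_ids <- ctx$rxn_ids
  removed <- character(0)
  grows_neg <- function() .ctx_grows(ctx, negative_medium, epsilon,
                                     closed = removed)
  positives_ok <- function(rm) {
    all(vapply(satisfied_positives, function(p)
      .ctx_grows(ctx, p, epsilon, closed = rm), logical(1)))
  }

  if (!grows_neg())
    return(list(network = network, removed = character(0),
                resolved = TRUE))

  removable <- intersect(removable_ids, all_ids)
  repeat {
    if (!grows_neg()) break
    sol <- .ctx_fba(ctx, negative_medium)
    if (sol$status == "infeasible") break
    fl <- stats::setNames(sol$x, all_ids)
    active <- setdiff(removable[abs(fl[removable]) > .FLUX_TOL], removed)
    if (!length(active)) {                   # nothing left to try
      return(list(network = network, removed = character(0),
                  resolved = FALSE))
    }
    ord <- withr::with_seed(seed + length(removed), sample(active))
    kept_one <- FALSE
    for (id in ord) {
      trial <- c(removed, id)
      if (positives_ok(trial)) {
        removed <- trial
        kept_one <- TRUE
        break
      }
    }
    if (!kept_one) {                          # every candidate breaks a positive
      return(list(network = network, removed = character(0),
                  resolved = FALSE))
    }
  }
  list(network = remove_reactions(network, removed),
       removed = sort(removed), resolved = TRUE)
}
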
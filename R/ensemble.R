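# Ensemble reconstruction and weighted prediction. Each ensemble member
# is gapfilled from the same draft on a random without-replacement draw
# of training growth (positive) and non-growth (negative) conditions;
# predictions aggregate member FBA results, weighted by the fraction of
# members that predict growth (or, for fluxes, that use the reaction).

#' Create a gapfill record
#' @param added_reaction_ids,removed_reaction_ids Ordered id vectors.
#' @param positives_used,negatives_used Training condition ids.
#' @param seed Integer member seed.
#' @param unresolved_negatives Condition ids the trimming could not
#'   silence.
#' @return A `gapfill_record`.
#' @export
gapfill_record <- function(added_reaction_ids = character(0),
                           removed_reaction_ids = character(0),
                           positives_used = character(0),
                           negatives_used = character(0),
                           seed = NA_integer_,
                           unresolved_negatives = character(0)) {
  if (length(intersect(added_reaction_ids, removed_reaction_ids)))
    stop("added and removed reaction sets must be disjoint")
  structure(list(added_reaction_ids = added_reaction_ids,
                 removed_reaction_ids = removed_reaction_ids,
                 positives_used = positives_used,
                 negatives_used = negatives_used,
                 seed = as.integer(seed),
                 unresolved_negatives = unresolved_negatives),
            class = "gapfill_record")
}

.child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483629)
}

#' Build an ensemble of gapfilled networks
#'
#' For member i, a without-replacement subset of `n_pos` positive and
#' `n_neg` negative training conditions is drawn under a member seed
#' derived from `seed`. Positives are gapfilled in drawn order against
#' `db`, then negatives are trimmed in drawn order (only reactions added
#' during this member's gapfilling are removable), and all positives are
#' re-verified. A member whose draw contains an ungapfillable positive is
#' regenerated with a fresh draw, up to `max_retries` times.
#'
#' @param draft Draft `metabolic_network` shared by all members.
#' @param db A [universal_db()].
#' @param positives,negatives Named lists of [medium_condition()] objects
#'   (growth / non-growth training panels).
#' @param size Number of ensemble members (the study-scale configuration
#'   is 50 members trained on 26 positives and 11 negatives).
#' @param n_pos,n_neg Training subset sizes.
#' @param seed Master integer seed; members use seeds derived from it.
#' @param epsilon Growth threshold.
#' @param exact_limit Passed to [gapfill_positive()].
#' @param max_retries Redraws allowed per member.
#' @return A `model_ensemble`: `networks` (list), `records` (parallel
#'   list of [gapfill_record()]), `size`.
#' @export
build_ensemble <- function(draft, db, positives, negatives, size = 50L,
                           n_pos = min(26L, length(positives)),
                           n_neg = min(11L, length(negatives)),
                           seed = 1L, epsilon = 1e-3, exact_limit = 12L,
                           max_retries = 3L) {
  stopifnot(size >= 1L, n_pos <= length(positives),
            n_neg <= length(negatives))
  pos_ids <- vapply(positives, `[[`, character(1), "id")
  neg_ids <- vapply(negatives, `[[`, character(1), "id")
  names(positives) <- pos_ids
  names(negatives) <- neg_ids

  networks <- vector("list", size)
  records <- vector("list", size)
  for (i in seq_len(size)) {
    member <- NULL
    for (attempt in 0:max_retries) {
      mseed <- .child_seed(seed, i * (max_retries + 1L) + attempt)
      member <- tryCatch(
        .build_member(draft, db, positives, negatives, n_pos, n_neg,
                      mseed, epsilon, exact_limit),
        nitrofill_ungapfillable = function(e) NULL)
      if (!is.null(member)) break
    }
    if (is.null(member))
      stop("member ", i, ": training draw ungapfillable after ",
           max_retries + 1L, " attempts")
    networks[[i]] <- member$network
    records[[i]] <- member$record
  }
  structure(list(networks = networks, records = records,
                 size = as.integer(size)),
            class = "model_ensemble")
}

.build_member <- function(draft, db, positives, negatives, n_pos, n_neg,
                          mseed, epsilon, exact_limit) {
  draw <- withr::with_seed(mseed, list(
    pos = sample(names(positives), n_pos),
    neg = if (n_neg > 0L) sample(names(negatives), n_neg) else character(0)))
  net <- draft
  added <- character(0)
  for (cid in draw$pos) {
    gf <- gapfill_positive(net, db, positives[[cid]], epsilon, exact_limit)
    net <- gf$network
    added <- union(added, gf$added)
  }
  removed <- character(0)
  unresolved <- character(0)
  sat_pos <- positives[draw$pos]
  for (cid in draw$neg) {
    ng <- gapfill_negative(net, negatives[[cid]], sat_pos,
                           removable_ids = setdiff(added, removed),
                           epsilon = epsilon, seed = mseed)
    net <- ng$network
    removed <- union(removed, ng$removed)
    if (!ng$resolved) unresolved <- c(unresolved, cid)
  }
  for (cid in draw$pos)                       # re-verification pass
    if (!predicts_growth(net, positives[[cid]], epsilon))
      stop("member invariant violated: positive '", cid,
           "' lost during trimming")
  list(network = net,
       record = gapfill_record(sort(setdiff(added, removed)),
                               sort(removed), draw$pos, draw$neg,
                               mseed, unresolved))
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", x$size, " members; draft-derived networks of ",
      paste(range(vapply(x$networks, function(n) length(n$reactions),
                         integer(1))), collapse = "-"),
      " reactions\n", sep = "")
  invisible(x)
}

#' Ensemble growth prediction
#'
#' The growth fraction is the share of members whose FBA optimum exceeds
#' `epsilon`; the weighted metabolic activity is the mean growth rate
#' over growing members multiplied by that fraction — identically the
#' mean over all members with non-growers contributing zero. The binary
#' call is `fraction >= vote_threshold`.
#'
#' @param ensemble A `model_ensemble`.
#' @param medium A [medium_condition()].
#' @param epsilon Growth threshold.
#' @param vote_threshold Fraction of members needed for a positive call.
#' @return List with `fraction_growing`, `activity`, `binary_call`, and
#'   the per-member `growth_rates`.
#' @export
ensemble_predict <- function(ensemble, medium, epsilon = 1e-3,
                             vote_threshold = 0.5) {
  stopifnot(ensemble$size >= 1L)
  rates <- vapply(ensemble$networks, function(n)
    fba(n, medium)$objective_value, numeric(1))
  growing <- rates > epsilon
  fraction <- mean(growing)
  activity <- mean(ifelse(growing, rates, 0))
  list(fraction_growing = fraction, activity = activity,
       binary_call = fraction >= vote_threshold, growth_rates = rates)
}

#' Ensemble-weighted reaction fluxes
#'
#' For each reaction the weight is the fraction of all members in which
#' it carries non-zero flux under that member's FBA optimum; the
#' weighted flux is the mean flux over those active members times the
#' weight. Members lacking the reaction count in the denominator only.
#'
#' @inheritParams ensemble_predict
#' @param tol Absolute flux below which a reaction is considered
#'   inactive.
#' @return Named numeric vector of weighted fluxes over the union of
#'   member reactions.
#' @export
ensemble_flux <- function(ensemble, medium, tol = .FLUX_TOL) {
  stopifnot(ensemble$size >= 1L)
  sols <- lapply(ensemble$networks, function(n) fba(n, medium)$fluxes)
  all_ids <- sort(unique(unlist(lapply(sols, names))))
  out <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (id in all_ids) {
    v <- vapply(sols, function(fl) if (id %in% names(fl)) fl[[id]]
                else NA_real_, numeric(1))
    active <- !is.na(v) & abs(v) > tol
    if (any(active))
      out[[id]] <- mean(v[active]) * (sum(active) / ensemble$size)
  }
  out
}

#' Flux fold changes between two conditions
#'
#' Compares two weighted flux maps from the same ensemble on the log2
#' scale, flooring magnitudes at `floor` so that inactive reactions do
#' not produce infinite ratios; reversible (negative) weighted fluxes
#' enter by absolute value. Reactions whose |log2 fold change| exceeds
#' `threshold` are returned sorted by |log2FC| descending.
#'
#' @param flux_a,flux_b Named weighted flux vectors (see
#'   [ensemble_flux()]).
#' @param threshold Log2 fold-change cutoff (default 1).
#' @param floor Pseudo-flux applied to magnitudes below it.
#' @return data.frame with `reaction_id` and `log2fc`.
#' @export
flux_fold_changes <- function(flux_a, flux_b, threshold = 1,
                              floor = 1e-6) {
  ids <- sort(union(names(flux_a), names(flux_b)))
  a <- pmax(abs(ifelse(ids %in% names(flux_a), flux_a[ids], 0)), floor)
  b <- pmax(abs(ifelse(ids %in% names(flux_b), flux_b[ids], 0)), floor)
  l2 <- log2(a / b)
  keep <- abs(l2) > threshold
  out <- data.frame(reaction_id = ids[keep], log2fc = l2[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$log2fc)), , drop = FALSE]
}

#' Serialize / load an ensemble
#'
#' Writes one JSON file per member network plus a `records.json`
#' manifest; byte-stable for a given seed so identical builds compare
#' equal on disk.
#'
#' @param ensemble A `model_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `read_ensemble` returns the `model_ensemble`.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(ensemble$size))
    write_network_json(ensemble$networks[[i]],
                       file.path(dir, sprintf("member_%03d.json", i)))
  jsonlite::write_json(
    lapply(ensemble$records, unclass),
    file.path(dir, "records.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  recs <- jsonlite::read_json(file.path(dir, "records.json"))
  records <- lapply(recs, function(r)
    gapfill_record(unlist(r$added_reaction_ids) %||% character(0),
                   unlist(r$removed_reaction_ids) %||% character(0),
                   unlist(r$positives_used) %||% character(0),
                   unlist(r$negatives_used) %||% character(0),
                   r$seed %||% NA_integer_,
                   unlist(r$unresolved_negatives) %||% character(0)))
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.json$",
                           full.names = TRUE))
  networks <- lapply(files, read_network_json)
  stopifnot(length(networks) == length(records))
  structure(list(networks = networks, records = records,
                 size = length(networks)), class = "model_ensemble")
}
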
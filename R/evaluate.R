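# Model-vs-experiment evaluation with training-condition masking,
# random prediction baselines, and rank-based activity correlation.

#' Evaluate ensemble growth predictions against experimental truth
#'
#' For each condition, members whose training record contains that
#' condition abstain (per-member masking, avoiding the bias of scoring a
#' member on data it was gapfilled with); the ensemble call is taken
#' from the remaining votes. A `mask = "none"` mode scores all members,
#' and `mask = "holdout"` drops a fixed set of conditions from
#' evaluation entirely (the global-holdout design used when a handful of
#' substrates is reserved for downstream integration).
#'
#' @param ensemble A `model_ensemble` with training records.
#' @param panel Named list of [medium_condition()] objects covering the
#'   conditions to score.
#' @param truth Named logical vector: condition id -> experimentally
#'   observed growth.
#' @param epsilon Growth threshold.
#' @param vote_threshold Fraction of (unmasked) members required for a
#'   positive call.
#' @param mask `"record"` (default), `"none"`, or `"holdout"`.
#' @param holdout Condition ids excluded when `mask = "holdout"`.
#' @return A `metrics_report`: confusion counts, `accuracy`,
#'   `precision`, `recall` (NA when undefined), the per-condition
#'   prediction table, and the number of conditions excluded because
#'   every member was masked.
#' @export
evaluate_ensemble <- function(ensemble, panel, truth, epsilon = 1e-3,
                              vote_threshold = 0.5,
                              mask = c("record", "none", "holdout"),
                              holdout = character(0)) {
  mask <- match.arg(mask)
  ids <- names(truth)
  if (!all(ids %in% names(panel)))
    stop("panel lacks media for: ",
         paste(setdiff(ids, names(panel)), collapse = ", "))
  if (mask == "holdout") ids <- setdiff(ids, holdout)

  trained_on <- lapply(ensemble$records, function(r)
    c(r$positives_used, r$negatives_used))
  rows <- list()
  excluded <- character(0)
  for (cid in ids) {
    rates <- vapply(ensemble$networks, function(n)
      fba(n, panel[[cid]])$objective_value, numeric(1))
    masked <- if (mask == "record")
      vapply(trained_on, function(tr) cid %in% tr, logical(1))
    else rep(FALSE, ensemble$size)
    use <- !masked
    if (!any(use)) {
      warning("condition '", cid, "': all members trained on it; ",
              "excluded from evaluation")
      excluded <- c(excluded, cid)
      next
    }
    votes <- rates[use] > epsilon
    fraction <- mean(votes)
    rows[[cid]] <- data.frame(
      condition_id = cid,
      n_members_used = sum(use),
      fraction = fraction,
      activity = mean(ifelse(votes, rates[use], 0)),
      call = fraction >= vote_threshold,
      truth = truth[[cid]],
      stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, rows)
  rownames(pred) <- NULL
  tp <- sum(pred$call & pred$truth)
  fp <- sum(pred$call & !pred$truth)
  fn <- sum(!pred$call & pred$truth)
  tn <- sum(!pred$call & !pred$truth)
  structure(list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = (tp + tn) / nrow(pred),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    predictions = pred,
    excluded_conditions = excluded),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n=", sum(x$confusion),
      " accuracy=", signif(x$accuracy, 3),
      " precision=", signif(x$precision, 3),
      " recall=", signif(x$recall, 3), "\n", sep = "")
  cat("  confusion: TP=", x$confusion["TP"], " FP=", x$confusion["FP"],
      " FN=", x$confusion["FN"], " TN=", x$confusion["TN"], "\n",
      sep = "")
  invisible(x)
}

#' Random prediction baseline
#'
#' Draws i.i.d. Bernoulli growth predictions for every condition and
#' returns the empirical distribution of accuracy, precision and recall.
#' The growth probability defaults to the prevalence of growth in the
#' truth vector; set `p_grow = 0.5` for the information-free coin.
#'
#' @param truth Named logical vector of observed growth.
#' @param n_draws Number of random prediction sets (>= 100).
#' @param seed Integer seed.
#' @param p_grow Bernoulli probability (default: prevalence).
#' @return List with `draws` (data.frame of per-draw metrics) and
#'   `summary` (mean and 2.5/95/97.5 percentiles per metric).
#' @export
random_baseline <- function(truth, n_draws = 1000L, seed = 1L,
                            p_grow = NULL) {
  stopifnot(n_draws >= 100L)
  y <- as.logical(truth)
  n <- length(y)
  if (is.null(p_grow)) p_grow <- mean(y)
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(n_draws), function(i) {
      pr <- stats::runif(n) < p_grow
      tp <- sum(pr & y); fp <- sum(pr & !y)
      fn <- sum(!pr & y); tn <- sum(!pr & !y)
      c(accuracy = (tp + tn) / n,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    }, numeric(3)))
  })
  draws <- as.data.frame(draws)
  summ <- lapply(draws, function(v)
    c(mean = mean(v, na.rm = TRUE),
      q2.5 = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
      q95 = unname(stats::quantile(v, 0.95, na.rm = TRUE)),
      q97.5 = unname(stats::quantile(v, 0.975, na.rm = TRUE))))
  list(draws = draws, summary = summ, p_grow = p_grow)
}

#' Squared correlation of percentile ranks
#'
#' Converts two paired vectors (matched by name) to percentile ranks
#' (average ranks for ties) and returns the squared Pearson correlation
#' of the rank vectors. Returns NA when either vector is constant.
#'
#' @param activity Named numeric vector (e.g. ensemble-weighted
#'   activity per condition).
#' @param experimental Named numeric vector (e.g. mean AUC z-score per
#'   condition).
#' @return Squared correlation in [0, 1], or NA.
#' @export
rank_r2 <- function(activity, experimental) {
  shared <- intersect(names(activity), names(experimental))
  if (length(shared) < 3L) stop("need at least 3 shared conditions")
  a <- rank(activity[shared], ties.method = "average") / length(shared)
  b <- rank(experimental[shared], ties.method = "average") /
    length(shared)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)^2
}
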
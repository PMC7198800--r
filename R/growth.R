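# Phenotype-microarray and batch growth-curve scoring.
#
# Kinetic series are fitted to the logistic model
#   N(t) = K / (1 + ((K - N0)/N0) * exp(-r t))
# and summarized by carrying capacity K, intrinsic rate r, and the area
# under the fitted curve. A well is growth-positive when K exceeds the
# absorbance threshold in enough replicates; intensities 0-4 come from
# within-strain z-scored AUCs of the growth-positive wells split into
# quartiles.

#' Subtract the negative-control well from a plate run
#'
#' Every non-control series has the control (default well A1) value at
#' the matching time point subtracted; the control series itself is
#' retained unmodified for QC. Time grids must agree within each
#' (plate, replicate) group.
#'
#' @param run Long-form data.frame with columns `plate_id`, `well`,
#'   `replicate`, `substrate_id`, `time_h`, `value`.
#' @param control_well Control well id (default "A1").
#' @return The run with background-subtracted values.
#' @export
subtract_background <- function(run, control_well = "A1") {
  .check_plate_df(run)
  groups <- split(run, list(run$plate_id, run$replicate), drop = TRUE)
  out <- lapply(groups, function(g) {
    ctrl <- g[g$well == control_well, ]
    if (nrow(ctrl) == 0L)
      stop("control well '", control_well, "' missing in plate ",
           g$plate_id[1L], " replicate ", g$replicate[1L])
    ctrl <- ctrl[order(ctrl$time_h), ]
    for (w in setdiff(unique(g$well), control_well)) {
      idx <- which(g$well == w)
      idx <- idx[order(g$time_h[idx])]
      if (length(idx) != nrow(ctrl) ||
          max(abs(g$time_h[idx] - ctrl$time_h)) > 1e-9)
        stop("time grid of well ", w, " does not match control well")
      g$value[idx] <- g$value[idx] - ctrl$value
    }
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.check_plate_df <- function(run) {
  need <- c("plate_id", "well", "replicate", "substrate_id", "time_h",
            "value")
  if (!is.data.frame(run) || !all(need %in% names(run)))
    stop("plate data must contain columns: ", paste(need, collapse = ", "))
  invisible(run)
}

.logistic_curve <- function(t, K, r, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

# Analytic integral of the fitted logistic over [0, Tmax]:
#   (K/r) * [ log(exp(rT) + A) - log(1 + A) ],  A = (K - N0)/N0,
# computed via log1p for numerical stability at large r*T.
.logistic_auc <- function(K, r, N0, t_max) {
  A <- (K - N0) / N0
  (K / r) * (r * t_max + log1p(A * exp(-r * t_max)) - log1p(A))
}

#' Fit the logistic growth model to one well series
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nlsLM}) of the logistic model. Negative values
#' (possible after background subtraction) are clipped at 0 before
#' fitting. The AUC is the analytic integral of the fitted curve over
#' the observed time span. Fits that do not converge, or degenerate
#' flat series, are flagged `converged = FALSE` with K set to the
#' maximum observed value, r = 0, and an empirical trapezoid AUC.
#'
#' @param time Hours, strictly increasing, length >= 10.
#' @param value Absorbance (A590 or OD600), same length.
#' @return A `logistic_fit`: `K`, `r`, `N0`, `auc`, `converged`, `rss`.
#' @export
fit_logistic <- function(time, value) {
  if (length(time) < 10L) stop("need at least 10 time points")
  if (length(value) != length(time) || any(!is.finite(value)))
    stop("value must be finite and match time in length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  value <- pmax(value, 0)
  t0 <- time - time[1L]
  vmax <- max(value)

  fail <- function() {
    auc_emp <- sum(diff(t0) * (utils::head(value, -1) +
                                 utils::tail(value, -1)) / 2)
    structure(list(K = vmax, r = 0, N0 = value[1L], auc = auc_emp,
                   converged = FALSE, rss = NA_real_),
              class = "logistic_fit")
  }
  if (vmax <= 0 || (vmax - min(value)) < 1e-6) return(fail())

  start <- list(K = max(vmax, 1e-3), r = 0.2,
                N0 = max(value[1L], 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
      data = data.frame(t = t0, v = value), start = start,
      lower = c(K = 1e-6, r = 1e-6, N0 = 1e-6),
      upper = c(K = 2 * max(vmax, 1e-3), r = 5, N0 = max(vmax, 1e-3)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  structure(list(K = unname(cf["K"]), r = unname(cf["r"]),
                 N0 = unname(cf["N0"]),
                 auc = unname(.logistic_auc(cf["K"], cf["r"],
                                            cf["N0"], max(t0))),
                 converged = TRUE,
                 rss = sum(stats::resid(fit)^2)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> K=", signif(x$K, 4), " r=", signif(x$r, 4),
      " N0=", signif(x$N0, 4), " auc=", signif(x$auc, 5),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Growth call from replicate fits
#'
#' A well is growth-positive when the fitted carrying capacity exceeds
#' `k_threshold` in at least `min_replicates` replicates (the default
#' 0.1 / 2-of-3 rule used for A590 phenotype arrays).
#'
#' @param fits List of [fit_logistic()] results, or a numeric vector of
#'   K values.
#' @param k_threshold Carrying-capacity threshold.
#' @param min_replicates Minimum replicates above threshold.
#' @return Logical.
#' @export
call_growth <- function(fits, k_threshold = 0.1, min_replicates = 2L) {
  K <- if (is.numeric(fits)) fits else
    vapply(fits, `[[`, numeric(1), "K")
  if (!length(K)) stop("at least one fit required")
  sum(K > k_threshold) >= min_replicates
}

#' Score growth intensities on a 0-4 scale
#'
#' Within each strain, replicate AUCs of growth-positive wells are
#' z-scored within each replicate assay, averaged across replicates, and
#' the averaged z-scores are split into empirical quartiles: intensity 1
#' (lowest quartile) through 4 (highest); non-growth wells score 0.
#' Quartile boundaries use type-7 quantiles with ties assigned to the
#' lower bin. If all averaged z-scores coincide (degenerate input) every
#' growth-positive well scores 1, with a warning.
#'
#' @param auc_table data.frame with columns `strain`, `substrate`,
#'   `replicate`, `auc`.
#' @param calls data.frame with columns `strain`, `substrate`, `call`
#'   (logical growth calls).
#' @param exclude Substrates dropped before scoring (e.g. wells with
#'   known high background).
#' @return A `growth_matrix` data.frame: `strain`, `substrate`, `call`,
#'   `intensity` (0-4), `mean_z`.
#' @export
score_intensities <- function(auc_table, calls, exclude = character(0)) {
  stopifnot(all(c("strain", "substrate", "replicate", "auc") %in%
                  names(auc_table)),
            all(c("strain", "substrate", "call") %in% names(calls)))
  auc_table <- auc_table[!auc_table$substrate %in% exclude, ]
  calls <- calls[!calls$substrate %in% exclude, ]

  out <- lapply(split(calls, calls$strain), function(cl) {
    strain <- cl$strain[1L]
    pos <- cl$substrate[cl$call]
    if (length(pos) < 4L)
      stop("strain '", strain, "': fewer than 4 growth-positive ",
           "substrates; quartile scoring undefined")
    a <- auc_table[auc_table$strain == strain &
                     auc_table$substrate %in% pos, ]
    zs <- lapply(split(a, a$replicate), function(rep_df) {
      z <- rep_df$auc
      s <- stats::sd(z)
      z <- if (is.na(s) || s < 1e-12) rep(0, length(z)) else
        (z - mean(z)) / s
      stats::setNames(z, rep_df$substrate)
    })
    mean_z <- vapply(pos, function(sb)
      mean(vapply(zs, function(z) z[[sb]], numeric(1))), numeric(1))
    if (max(mean_z) - min(mean_z) < 1e-12) {
      warning("strain '", strain, "': constant averaged z-scores; ",
              "all growth-positive wells scored 1")
      intensity <- stats::setNames(rep(1L, length(pos)), pos)
    } else {
      q <- stats::quantile(mean_z, c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      intensity <- stats::setNames(
        1L + (mean_z > q[1]) + (mean_z > q[2]) + (mean_z > q[3]), pos)
    }
    data.frame(strain = strain, substrate = cl$substrate,
               call = cl$call,
               intensity = ifelse(cl$call,
                                  intensity[cl$substrate], 0L),
               mean_z = ifelse(cl$call, mean_z[cl$substrate], NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("growth_matrix", "data.frame")
  res
}

#' Fit and score a whole plate run
#'
#' Convenience wrapper: background subtraction, per-well logistic fits,
#' growth calls, and intensity scoring for a long-form multi-strain
#' plate data.frame (one `plate_id` per strain).
#'
#' @param run Long-form plate data (see [subtract_background()]); the
#'   `plate_id` column is interpreted as the strain.
#' @param control_well Negative-control well id.
#' @param exclude Substrates excluded from scoring.
#' @param k_threshold,min_replicates Passed to [call_growth()].
#' @return List with `fits` (per strain/substrate/replicate data.frame)
#'   and `growth_matrix`.
#' @export
score_plate_run <- function(run, control_well = "A1",
                            exclude = character(0), k_threshold = 0.1,
                            min_replicates = 2L) {
  sub <- subtract_background(run, control_well)
  sub <- sub[sub$well != control_well, ]
  key <- interaction(sub$plate_id, sub$substrate_id, sub$replicate,
                     drop = TRUE)
  fits <- lapply(split(sub, key), function(d) {
    d <- d[order(d$time_h), ]
    f <- fit_logistic(d$time_h, d$value)
    data.frame(strain = d$plate_id[1L], substrate = d$substrate_id[1L],
               replicate = d$replicate[1L], K = f$K, r = f$r,
               auc = f$auc, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  calls <- do.call(rbind, lapply(
    split(fits, list(fits$strain, fits$substrate), drop = TRUE),
    function(d) data.frame(strain = d$strain[1L],
                           substrate = d$substrate[1L],
                           call = call_growth(d$K, k_threshold,
                                              min_replicates),
                           stringsAsFactors = FALSE)))
  rownames(calls) <- NULL
  gm <- score_intensities(fits[, c("strain", "substrate", "replicate",
                                   "auc")], calls, exclude = exclude)
  list(fits = fits, growth_matrix = gm)
}

#' Read / write plate kinetic data
#'
#' Long-form CSV with columns `plate_id`, `well`, `replicate`,
#' `substrate_id`, `time_h`, `value`.
#'
#' @param run Plate data.frame.
#' @param path CSV path.
#' @export
write_plate_csv <- function(run, path) {
  .check_plate_df(run)
  utils::write.csv(run, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  run <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_plate_df(run)
  run
}

#' Read / write a growth matrix
#' @param gm A `growth_matrix` data.frame.
#' @param path TSV path.
#' @export
write_growth_matrix_tsv <- function(gm, path) {
  utils::write.table(gm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_matrix_tsv
#' @export
read_growth_matrix_tsv <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(gm) <- c("growth_matrix", "data.frame")
  gm
}
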
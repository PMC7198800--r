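# Flux balance analysis: maximize biomass flux v_bio subject to the
# steady-state constraint S v = 0 and flux bounds. Media are imposed on
# exchange bounds: an exchange listed in the medium may take up at most
# its stated rate (lower bound = -max_uptake); unlisted exchanges are
# closed to uptake but stay open to secretion.

.FLUX_TOL <- 1e-6

# Build the LP data once for a set of reactions; gapfilling reuses the
# context and closes/opens columns by bound manipulation.
.lp_context <- function(reactions, metabolite_ids) {
  n <- length(reactions)
  m <- length(metabolite_ids)
  S <- matrix(0, m, n, dimnames = list(metabolite_ids,
                                       vapply(reactions, `[[`,
                                              character(1), "id")))
  for (j in seq_len(n)) {
    st <- reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  list(S = S,
       lb = vapply(reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(reactions, `[[`, numeric(1), "upper_bound"),
       exchange = vapply(reactions, `[[`, logical(1), "is_exchange"),
       biomass = vapply(reactions, `[[`, logical(1), "is_biomass"),
       rxn_ids = colnames(S))
}

.ctx_medium_bounds <- function(ctx, medium) {
  lb <- ctx$lb
  ub <- ctx$ub
  ex <- which(ctx$exchange)
  lb[ex] <- 0                       # closed to uptake by default
  listed <- intersect(names(medium$uptake_bounds), ctx$rxn_ids)
  idx <- match(listed, ctx$rxn_ids)
  lb[idx] <- -medium$uptake_bounds[listed]
  list(lb = lb, ub = ub)
}

.ctx_fba <- function(ctx, medium, closed = NULL) {
  bb <- .ctx_medium_bounds(ctx, medium)
  if (length(closed)) {
    idx <- match(closed, ctx$rxn_ids)
    bb$lb[idx] <- 0
    bb$ub[idx] <- 0
  }
  obj <- as.numeric(ctx$biomass)
  res <- solve_lp(obj, ctx$S, rep(0, nrow(ctx$S)), bb$lb, bb$ub)
  if (res$status %in% c("iteration_limit", "unbounded"))
    stop("FBA solver failure (", res$status, ") on condition '",
         medium$id, "'")
  res
}

#' Flux balance analysis
#'
#' Solves the linear program max v_biomass subject to S v = 0 and flux
#' bounds, with the medium imposed on exchange reactions. An infeasible
#' LP is reported as zero growth with `feasible = FALSE` rather than an
#' error; solver failures (iteration limit, unbounded) raise errors.
#'
#' @param network A `metabolic_network`.
#' @param medium A [medium_condition()].
#' @return A `flux_distribution` with elements `fluxes` (named numeric),
#'   `objective_value` (growth rate, toy 1/h units) and `feasible`.
#' @examples
#' net <- metabolic_network("toy",
#'   list(metabolite("A_e", compartment = "e"), metabolite("A_c"),
#'        metabolite("B_c")),
#'   list(reaction("EX_A", c(A_e = -1), -10, 1000, is_exchange = TRUE),
#'        reaction("T_A", c(A_e = -1, A_c = 1)),
#'        reaction("R_AB", c(A_c = -1, B_c = 1)),
#'        reaction("BIO", c(B_c = -1), is_biomass = TRUE)))
#' med <- medium_condition("A", c(EX_A = 10), "EX_A")
#' fba(net, med)$objective_value
#' @export
fba <- function(network, medium) {
  validate_network(network)
  ctx <- .lp_context(network$reactions, names(network$metabolites))
  res <- .ctx_fba(ctx, medium)
  if (res$status == "infeasible") {
    return(structure(list(
      fluxes = stats::setNames(rep(0, length(ctx$rxn_ids)), ctx$rxn_ids),
      objective_value = 0, feasible = FALSE),
      class = "flux_distribution"))
  }
  fl <- stats::setNames(res$x, ctx$rxn_ids)
  resid <- max(abs(ctx$S %*% res$x))
  if (resid > .FLUX_TOL)
    stop("FBA steady-state residual ", format(resid), " exceeds tolerance")
  structure(list(fluxes = fl,
                 objective_value = max(0, res$objective),
                 feasible = TRUE),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> objective ", format(x$objective_value),
      if (!x$feasible) " (infeasible)", "; ",
      sum(abs(x$fluxes) > .FLUX_TOL), "/", length(x$fluxes),
      " reactions carrying flux\n", sep = "")
  invisible(x)
}

#' Does a network grow on a medium?
#'
#' TRUE iff the FBA biomass optimum strictly exceeds `epsilon`; the
#' threshold separates numerical noise from genuine growth.
#'
#' @inheritParams fba
#' @param epsilon Growth threshold (> 0), default 1e-3 in toy flux units.
#' @return Logical.
#' @export
predicts_growth <- function(network, medium, epsilon = 1e-3) {
  stopifnot(epsilon > 0)
  fba(network, medium)$objective_value > epsilon
}

.ctx_grows <- function(ctx, medium, epsilon, closed = NULL) {
  res <- .ctx_fba(ctx, medium, closed)
  if (res$status == "infeasible") return(FALSE)
  res$objective > epsilon
}
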
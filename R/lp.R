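# Dense two-phase primal simplex used for all flux LPs in this package.
#
# Problem form:  maximize  c'v   subject to   S v = b,   lb <= v <= ub
# with all bounds finite (flux LPs here use +/- 1000 as the open bound).
# Scale is small (tens of metabolites, ~10^2 reactions), so a dense
# tableau with vectorized pivots is adequate and has no external
# dependencies. Bland's rule is enabled after a burn-in of Dantzig
# pivots to guarantee termination on degenerate instances.

#' @keywords internal
#' @noRd
solve_lp <- function(c_obj, S, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  n <- length(c_obj)
  stopifnot(is.matrix(S), ncol(S) == n, length(b) == nrow(S),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp: bounds must be finite")
  if (any(ub < lb - tol))
    stop("solve_lp: upper bound below lower bound")
  if (!maximize) {
    res <- solve_lp(-c_obj, S, b, lb, ub, TRUE, tol, max_iter)
    if (!is.na(res$objective)) res$objective <- -res$objective
    return(res)
  }

  ## shift to x = v - lb so x >= 0; drop columns fixed at their bound
  u <- ub - lb
  b2 <- b - as.vector(S %*% lb)
  keep <- which(u > tol)
  v_out <- lb
  nk <- length(keep)
  if (nk == 0L) {
    feas <- length(b2) == 0L || max(abs(b2)) <= 1e-7
    return(list(status = if (feas) "optimal" else "infeasible",
                x = v_out,
                objective = if (feas) sum(c_obj * v_out) else NA_real_))
  }
  A <- S[, keep, drop = FALSE]
  cc <- c_obj[keep]
  uu <- u[keep]
  m <- nrow(A)

  flip <- b2 < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b2[flip] <- -b2[flip]
  }

  ## tableau: rows = m equality rows + nk upper-bound rows (x_j + s_j = u_j)
  ## cols = x (nk) | ub slacks (nk) | artificials (m) | rhs
  ncons <- m + nk
  na_ <- m
  ncols <- 2L * nk + na_ + 1L
  Tm <- matrix(0, ncons, ncols)
  if (m > 0L) {
    Tm[seq_len(m), seq_len(nk)] <- A
    Tm[cbind(seq_len(m), 2L * nk + seq_len(m))] <- 1
    Tm[seq_len(m), ncols] <- b2
  }
  Tm[cbind(m + seq_len(nk), seq_len(nk))] <- 1
  Tm[cbind(m + seq_len(nk), nk + seq_len(nk))] <- 1
  Tm[m + seq_len(nk), ncols] <- uu
  basis <- c(if (m > 0L) 2L * nk + seq_len(m), nk + seq_len(nk))

  pivot_at <- function(prow, j) {
    piv <- Tm[prow, j]
    Tm[prow, ] <<- Tm[prow, ] / piv
    colv <- Tm[, j]
    colv[prow] <- 0
    nz <- which(abs(colv) > 0)
    if (length(nz))
      Tm[nz, ] <<- Tm[nz, ] - outer(colv[nz], Tm[prow, ])
    basis[prow] <<- j
  }

  run_phase <- function(cvec, forbid) {
    zrow <- cvec - as.vector(cvec[basis] %*% Tm[, -ncols, drop = FALSE])
    zrow[forbid] <- -Inf
    it <- 0L
    bland_after <- 20L * ncons + 200L
    repeat {
      it <- it + 1L
      if (it > max_iter) return("iteration_limit")
      cand <- which(zrow > tol)
      if (!length(cand)) return("optimal")
      j <- if (it > bland_after) cand[1L] else cand[which.max(zrow[cand])]
      colj <- Tm[, j]
      pos <- which(colj > tol)
      if (!length(pos)) return("unbounded")
      ratio <- Tm[pos, ncols] / colj[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol]
      prow <- tie[which.min(basis[tie])]
      leaving <- basis[prow]
      pivot_at(prow, j)
      ## reduced-cost update
      zj <- zrow[j]
      zrow <- zrow - zj * Tm[prow, -ncols]
      zrow[j] <- 0
      zrow[leaving] <- cvec[leaving] -
        sum(cvec[basis] * Tm[, leaving])
      zrow[forbid] <- -Inf
    }
  }

  art_cols <- if (na_ > 0L) 2L * nk + seq_len(na_) else integer(0)

  ## Phase 1: drive artificials to zero
  if (na_ > 0L) {
    c1 <- rep(0, ncols - 1L)
    c1[art_cols] <- -1
    st1 <- run_phase(c1, forbid = rep(FALSE, ncols - 1L))
    if (st1 == "iteration_limit")
      return(list(status = "iteration_limit", x = NULL, objective = NA_real_))
    infeas <- sum(Tm[basis %in% art_cols, ncols])
    if (infeas > 1e-7)
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    ## pivot lingering zero-level artificials out where possible
    for (i in which(basis %in% art_cols)) {
      row_nz <- which(abs(Tm[i, seq_len(2L * nk)]) > 1e-7)
      if (length(row_nz)) pivot_at(i, row_nz[1L])
    }
  }

  ## Phase 2: original objective; artificial columns may not enter
  c2 <- rep(0, ncols - 1L)
  c2[seq_len(nk)] <- cc
  forbid <- rep(FALSE, ncols - 1L)
  forbid[art_cols] <- TRUE
  st2 <- run_phase(c2, forbid)
  if (st2 != "optimal")
    return(list(status = st2, x = NULL, objective = NA_real_))

  x <- numeric(nk)
  in_x <- basis <= nk
  x[basis[in_x]] <- Tm[in_x, ncols]
  v_out[keep] <- lb[keep] + x
  list(status = "optimal", x = v_out, objective = sum(c_obj * v_out))
}
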
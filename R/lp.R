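#' Maximise a linear objective over the flux polytope
#'
#' One-function linear-programming interface used by every analysis in the
#' package: maximise `c'v` subject to `S v = 0` (over non-boundary metabolite
#' rows) and `lb <= v <= ub`. A presolve pins zero-width variables, drops
#' vacuous rows and reduces the equality system to an independent row set;
#' the reduced programme is solved by an internal dense two-phase simplex
#' with Bland's rule (see `lp_box_simplex`). All bounds must be finite;
#' models built by this package default to -1000/1000, which keeps every
#' programme bounded.
#'
#' @param objective Numeric coefficient vector, length `n`.
#' @param S Constraint matrix (rows = steady-state metabolites).
#' @param lb,ub Numeric bound vectors, length `n`.
#' @param tol Feasibility/optimality tolerance handed to the simplex.
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"not_converged"`), `value` and `solution`.
#' @keywords internal
lp_maximize <- function(objective, S, lb, ub, tol = 1e-9) {
  n <- length(objective)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("LP bounds must be finite.")
  }
  if (any(lb > ub)) abort("LP has lb > ub.")
  S <- as.matrix(S)
  infeasible <- list(status = "infeasible", value = NA_real_,
                     solution = rep(NA_real_, n), tol = tol)

  # presolve: pin zero-width variables (e.g. closed exchanges) and move them
  # to the right-hand side — the simplex backend chokes on degenerate boxes
  fixed <- (ub - lb) <= 0
  v <- rep(NA_real_, n)
  v[fixed] <- lb[fixed]
  free <- which(!fixed)
  rhs <- if (nrow(S) > 0L && any(fixed)) {
    as.numeric(-S[, fixed, drop = FALSE] %*% lb[fixed])
  } else {
    rep(0, nrow(S))
  }
  Sf <- S[, free, drop = FALSE]
  # drop vacuous steady-state rows; a vacuous row with nonzero rhs is a
  # contradiction
  vac <- rowSums(abs(Sf)) == 0
  if (any(vac & abs(rhs) > tol)) return(infeasible)
  Sf <- Sf[!vac, , drop = FALSE]
  rhs <- rhs[!vac]
  if (nrow(Sf) > 0L) {
    # reduce to an independent set of equality rows (the backend cannot take
    # redundant or overdetermined systems); infeasible if rhs leaves the
    # row space
    ra <- qr(Sf)$rank
    if (qr(cbind(Sf, rhs))$rank > ra) return(infeasible)
    if (ra < nrow(Sf)) {
      keep <- qr(t(Sf))$pivot[seq_len(ra)]
      Sf <- Sf[keep, , drop = FALSE]
      rhs <- rhs[keep]
    }
  }

  if (length(free) == 0L) {
    return(list(status = "optimal", value = sum(objective * v), solution = v,
                tol = tol))
  }
  if (nrow(Sf) == 0L) {
    v[free] <- ifelse(objective[free] >= 0, ub[free], lb[free])
    return(list(status = "optimal", value = sum(objective * v), solution = v,
                tol = tol))
  }
  # shift x = v - lb >= 0
  lbf <- lb[free]; ubf <- ub[free]
  b3 <- rhs - as.numeric(Sf %*% lbf)
  A3 <- Sf
  flip <- b3 < 0
  if (any(flip)) {
    A3[flip, ] <- -A3[flip, , drop = FALSE]
    b3[flip] <- -b3[flip]
  }
  res <- lp_box_simplex(objective[free], A3, b3, ubf - lbf, tol = tol)
  if (res$status != "optimal") {
    if (res$status == "infeasible") return(infeasible)
    return(list(status = res$status, value = NA_real_,
                solution = rep(NA_real_, n), tol = tol))
  }
  v[free] <- res$x + lbf
  list(status = "optimal", value = sum(objective * v), solution = v, tol = tol)
}

# Steady-state rows of S: non-boundary metabolites only.
steady_state_matrix <- function(model) {
  S <- build_stoichiometric_matrix(model)
  S[!model$metabolites$boundary, , drop = FALSE]
}
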
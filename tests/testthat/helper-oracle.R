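# Brute-force LP oracle: enumerate candidate vertices of
#   { v : S v = 0, lb <= v <= ub }
# by fixing every size-k subset of variables (k = n - rank(S)) at one of its
# bounds and solving the remaining square system. Exponential, but exact for
# the <= 8-reaction fixtures it is used on, and entirely independent of the
# package's simplex.
oracle_fba_max <- function(model, media = NULL, tol = 1e-8) {
  if (!is.null(media)) model <- apply_media(model, media)
  S <- as.matrix(atrazfba::build_stoichiometric_matrix(model))
  S <- S[!model$metabolites$boundary, , drop = FALSE]
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cvec <- as.numeric(model$reactions$id == model$objective_id)
  n <- length(cvec)
  r <- if (nrow(S) > 0) qr(S)$rank else 0L
  k <- n - r
  best <- -Inf
  feasible_any <- FALSE
  check <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(invisible(NULL))
    if (nrow(S) > 0 && max(abs(S %*% v)) > tol) return(invisible(NULL))
    feasible_any <<- TRUE
    val <- sum(cvec * v)
    if (val > best) best <<- val
    invisible(NULL)
  }
  if (k == 0L) {
    v <- qr.solve(S, rep(0, nrow(S)))
    check(v)
  } else {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (fix in subsets) {
      freev <- setdiff(seq_len(n), fix)
      Sfree <- S[, freev, drop = FALSE]
      if (qr(Sfree)$rank < length(freev)) next
      # 2^k assignments of the fixed variables to lb or ub
      for (mask in 0:(2^k - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
        vfix <- ifelse(at_ub, ub[fix], lb[fix])
        rhs <- -S[, fix, drop = FALSE] %*% vfix
        vfree <- tryCatch(qr.solve(Sfree, rhs), error = function(e) NULL)
        if (is.null(vfree)) next
        v <- numeric(n)
        v[fix] <- vfix
        v[freev] <- vfree
        check(v)
      }
    }
  }
  list(value = if (feasible_any) best else NA_real_, feasible = feasible_any)
}
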
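# Dense two-phase primal simplex for the small LPs this package solves.
#
# maximize c'x  subject to  A x = b (b >= 0), 0 <= x <= u.
#
# Upper bounds are carried as explicit slack rows (x_i + s_i = u_i), which
# keeps the tableau logic textbook-simple; with the network sizes used here
# (tens of reactions) the dense tableau is far below any performance concern.
# Bland's rule is used throughout, so the method cannot cycle on the highly
# degenerate bases that metabolic networks produce.

lp_box_simplex <- function(cvec, A, b, u, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(u) == n, all(b >= -tol), all(u >= -tol))
  b <- pmax(b, 0)
  u <- pmax(u, 0)

  # columns: x (1..n), s (n+1..2n), artificials (2n+1..2n+m); rhs last
  N <- 2L * n + m
  Tm <- matrix(0, m + n, N + 1L)
  if (m > 0L) {
    Tm[seq_len(m), seq_len(n)] <- A
    Tm[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1
    Tm[seq_len(m), N + 1L] <- b
  }
  Tm[cbind(m + seq_len(n), seq_len(n))] <- 1
  Tm[cbind(m + seq_len(n), n + seq_len(n))] <- 1
  Tm[m + seq_len(n), N + 1L] <- u
  basis <- c(if (m > 0L) 2L * n + seq_len(m), n + seq_len(n))

  pivot <- function(Tm, d, basis, row, col) {
    piv <- Tm[row, col]
    Tm[row, ] <- Tm[row, ] / piv
    for (i in seq_len(nrow(Tm))) {
      if (i != row && abs(Tm[i, col]) > 0) {
        Tm[i, ] <- Tm[i, ] - Tm[i, col] * Tm[row, ]
      }
    }
    if (abs(d[col]) > 0) d <- d - d[col] * Tm[row, ]
    basis[row] <- col
    list(Tm = Tm, d = d, basis = basis)
  }

  # minimize w'x over the tableau from the current basis (Bland's rule)
  run_phase <- function(Tm, basis, w, allowed) {
    d <- c(w, 0)
    for (i in seq_along(basis)) {
      if (abs(w[basis[i]]) > 0) d <- d - w[basis[i]] * Tm[i, ]
    }
    repeat {
      enter <- 0L
      for (j in allowed) {
        if (d[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) break
      ratios <- ifelse(Tm[, enter] > tol,
                       Tm[, N + 1L] / Tm[, enter], Inf)
      if (all(!is.finite(ratios))) {
        return(list(status = "unbounded"))
      }
      rmin <- min(ratios)
      cand <- which(ratios <= rmin + tol)
      row <- cand[which.min(basis[cand])]
      st <- pivot(Tm, d, basis, row, enter)
      Tm <- st$Tm; d <- st$d; basis <- st$basis
    }
    value <- sum(w[basis] * Tm[, N + 1L])
    list(status = "optimal", Tm = Tm, basis = basis, value = value)
  }

  # phase 1: drive artificials to zero
  if (m > 0L) {
    w1 <- c(rep(0, 2L * n), rep(1, m))
    p1 <- run_phase(Tm, basis, w1, allowed = seq_len(N))
    if (p1$status != "optimal" || p1$value > 1e-6) {
      return(list(status = "infeasible"))
    }
    Tm <- p1$Tm
    basis <- p1$basis
    # pivot remaining zero-level artificials out of the basis (the constraint
    # rows are linearly independent by construction, so a pivot always exists)
    for (i in which(basis > 2L * n)) {
      cols <- which(abs(Tm[i, seq_len(2L * n)]) > tol)
      if (length(cols) > 0L) {
        st <- pivot(Tm, rep(0, N + 1L), basis, i, cols[1])
        Tm <- st$Tm; basis <- st$basis
      }
    }
    if (any(basis > 2L * n & Tm[, N + 1L] > 1e-6)) {
      return(list(status = "infeasible"))
    }
  }

  # phase 2: minimize -c'x over x/s columns only
  w2 <- c(-cvec, rep(0, n + m))
  p2 <- run_phase(Tm, basis, w2, allowed = seq_len(2L * n))
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- numeric(N)
  x[p2$basis] <- p2$Tm[, N + 1L]
  list(status = "optimal", x = x[seq_len(n)], value = -p2$value)
}
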
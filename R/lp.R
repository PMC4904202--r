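# Dense two-phase primal simplex with Bland's rule, for the small
# equality-constrained box LPs of flux balance analysis:
#
#     optimise  obj' v   s.t.  S v = 0-ish (general b),  lb <= v <= ub
#
# Written in-package because the general-purpose simplex routines available
# to us (boot::simplex, pracma::linprog) fail or cycle on degenerate
# equality-fixed problems of exactly this kind; Bland's pivoting rule makes
# termination unconditional, which matters more here than speed (models have
# tens of reactions at most).

# standard-form core: minimise c'x, A x = b (b >= 0 after row flips),
# 0 <= x <= u with finite u encoded as explicit slack rows.
# Returns list(x, value, status) with status "optimal" or "infeasible".
simplex_bland <- function(A, b, c_vec, u, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  # append slack rows x_i + s_i = u_i
  Af <- cbind(A, matrix(0, m, n))
  Bnd <- cbind(diag(n), diag(n))
  Afull <- rbind(Af, Bnd)
  bfull <- c(b, u)
  M <- m + n
  N <- 2 * n
  # flip rows to non-negative rhs
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]
  # phase 1: artificials on every row (slack rows could start basic, but a
  # uniform artificial basis keeps the code simple and these LPs are tiny)
  Tb <- cbind(Afull, diag(M))
  basis <- N + seq_len(M)
  cost1 <- c(rep(0, N), rep(1, M))
  res1 <- simplex_iterate(Tb, bfull, cost1, basis, tol)
  if (res1$value > 1e-7) {
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  }
  Tb <- res1$Tb
  bvec <- res1$b
  basis <- res1$basis
  # drive any residual artificial out of the basis (degenerate at zero)
  for (i in which(basis > N)) {
    piv <- which(abs(Tb[i, seq_len(N)]) > tol)
    piv <- piv[!(piv %in% basis)]
    if (length(piv) > 0) {
      j <- piv[1]
      fac <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / fac
      bvec[i] <- bvec[i] / fac
      for (k in seq_len(nrow(Tb))[-i]) {
        f2 <- Tb[k, j]
        if (abs(f2) > 0) {
          Tb[k, ] <- Tb[k, ] - f2 * Tb[i, ]
          bvec[k] <- bvec[k] - f2 * bvec[i]
        }
      }
      basis[i] <- j
    }
  }
  keep_rows <- basis <= N
  if (!all(keep_rows)) {
    # rows still held by artificials are redundant (zero rows); drop them
    Tb <- Tb[keep_rows, , drop = FALSE]
    bvec <- bvec[keep_rows]
    basis <- basis[keep_rows]
  }
  # phase 2 on the original columns (zero cost on the bound slacks)
  Tb <- Tb[, seq_len(N), drop = FALSE]
  cost2 <- c(c_vec, rep(0, N - n))
  res2 <- simplex_iterate(Tb, bvec, cost2, basis, tol)
  x <- numeric(N)
  x[res2$basis] <- res2$b
  list(x = x[seq_len(n)], value = res2$value, status = "optimal")
}

# Bland-rule simplex iterations on an explicit tableau.
simplex_iterate <- function(Tb, b, cost, basis, tol) {
  repeat {
    cb <- cost[basis]
    # reduced costs
    z <- drop(cb %*% Tb)
    rc <- cost - z
    enter_candidates <- which(rc < -tol)
    enter_candidates <- enter_candidates[!(enter_candidates %in% basis)]
    if (length(enter_candidates) == 0) {
      return(list(
        Tb = Tb, b = b, basis = basis,
        value = sum(cb * b)
      ))
    }
    j <- min(enter_candidates) # Bland: lowest index enters
    col <- Tb[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      # cannot happen for a boxed feasible region; guard anyway
      abort("simplex: unbounded direction in a bounded problem")
    }
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + 1e-12]
    i <- ties[which.min(basis[ties])] # Bland: lowest basis index leaves
    # pivot on (i, j)
    fac <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / fac
    b[i] <- b[i] / fac
    for (k in seq_len(nrow(Tb))[-i]) {
      f2 <- Tb[k, j]
      if (abs(f2) > 0) {
        Tb[k, ] <- Tb[k, ] - f2 * Tb[i, ]
        b[k] <- b[k] - f2 * b[i]
      }
    }
    basis[i] <- j
  }
}

# bounded-variable front end: optimise obj'v s.t. S v = rhs, lb <= v <= ub
# (all bounds finite). Returns list(flux, value, status).
solve_bounded_lp <- function(S, rhs, lb, ub, obj, maximize = TRUE) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  b <- rhs - drop(S %*% lb)
  u <- ub - lb
  cvec <- if (maximize) -obj else obj
  sol <- simplex_bland(S, b, cvec, u)
  if (sol$status != "optimal") {
    return(list(flux = NULL, value = NA_real_, status = sol$status))
  }
  v <- sol$x + lb
  list(flux = v, value = sum(obj * v), status = "optimal")
}
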
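# Independent brute-force oracles, kept free of the package's LP machinery.

# Optimum of  obj'v  over  {A v = b, lb <= v <= ub}  by exhaustive vertex
# enumeration: every vertex is a basic solution with n - rank(A) variables at
# a bound. Returns NA when the polytope is empty.
vertex_optimum <- function(A, b, lb, ub, obj, maximize = TRUE, tol = 1e-7) {
  n <- ncol(A)
  # reduce to an independent subset of rows (consistency re-checked below)
  qa <- qr(t(A))
  r <- qa$rank
  rows <- qa$pivot[seq_len(r)]
  Ar <- A[rows, , drop = FALSE]
  br <- b[rows]
  best <- NA_real_
  for (B in utils::combn(n, r, simplify = FALSE)) {
    AB <- Ar[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    NB <- setdiff(seq_len(n), B)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(NB))))
    if (length(NB) == 0) grid <- matrix(FALSE, 1, 0)
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(grid[g, ], ub[NB], lb[NB])
      rhs <- br - if (length(NB)) Ar[, NB, drop = FALSE] %*% vN else 0
      vB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n)
      v[B] <- vB
      v[NB] <- vN
      if (max(abs(A %*% v - b)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      val <- sum(obj * v)
      if (is.na(best)) {
        best <- val
      } else {
        best <- if (maximize) max(best, val) else min(best, val)
      }
    }
  }
  best
}

# capped bounds as used by the package's LP layer
oracle_bounds <- function(model, cap = 1000) {
  list(
    lb = pmax(model$reactions$lb, -cap),
    ub = pmin(model$reactions$ub, cap)
  )
}

# brute-force maximal growth of a model
oracle_max_growth <- function(model) {
  S <- stoich_matrix(model)
  bb <- oracle_bounds(model)
  obj <- as.numeric(model$reactions$id == model$growth_reaction)
  vertex_optimum(S, rep(0, nrow(S)), bb$lb, bb$ub, obj, maximize = TRUE)
}

# brute-force flux range of `target` with growth fixed at `growth`
oracle_flux_range <- function(model, target, growth) {
  S <- stoich_matrix(model)
  bb <- oracle_bounds(model)
  grow_row <- as.numeric(model$reactions$id == model$growth_reaction)
  A <- rbind(S, grow_row)
  b <- c(rep(0, nrow(S)), growth)
  obj <- as.numeric(model$reactions$id == target)
  c(
    vertex_optimum(A, b, bb$lb, bb$ub, obj, maximize = FALSE),
    vertex_optimum(A, b, bb$lb, bb$ub, obj, maximize = TRUE)
  )
}

# ordinary least squares via the normal equations (PLS full-rank oracle)
ols_coefficients <- function(x, y) {
  x1 <- cbind(1, as.matrix(x))
  drop(solve(crossprod(x1), crossprod(x1, y)))
}
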
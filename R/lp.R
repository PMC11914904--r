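# Dense two-phase primal simplex for the small LPs that arise in
# flux-balance analysis. Bland's rule throughout (deterministic, no
# cycling). Problems are solved in the form
#   max/min  obj' v   s.t.  S v = b,  lb <= v <= ub
# with finite lower bounds (upper bounds may be +Inf, enabling detection of
# unbounded objectives).

.simplex_iterate <- function(T, basis, cost, allowed, tol = 1e-9,
                             maxit = 100000L) {
  m <- nrow(T)
  nc <- ncol(T) - 1L
  rhs <- nc + 1L
  z <- cost - as.vector(crossprod(cost[basis], T[, seq_len(nc), drop = FALSE]))
  for (it in seq_len(maxit)) {
    cand <- which(allowed & z < -tol)
    if (!length(cand))
      return(list(status = "optimal", T = T, basis = basis))
    j <- cand[1L]                              # Bland: smallest index enters
    col <- T[, j]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(status = "unbounded", T = T, basis = basis))
    ratio <- T[pos, rhs] / col[pos]
    rmin <- min(ratio)
    tie <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
    r <- tie[which.min(basis[tie])]            # Bland: smallest index leaves
    piv_row <- T[r, ] / T[r, j]
    T <- T - tcrossprod(col, piv_row)
    T[r, ] <- piv_row
    z <- z - z[j] * piv_row[seq_len(nc)]
    basis[r] <- j
  }
  stop("simplex iteration limit reached", call. = FALSE)
}

#' Solve a bounded linear program (simplex method)
#'
#' Two-phase dense primal simplex with Bland's anti-cycling rule. Used by
#' [solve_fba()]; exposed for testing against enumeration oracles.
#'
#' @param obj Objective coefficients (length n).
#' @param S Constraint matrix (m x n), equality constraints `S v = b`.
#' @param b Right-hand side (length m, default all zero).
#' @param lb,ub Variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize Maximize (default) or minimize.
#' @param tol Pivot tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and `solution` (the flux vector, `NULL` unless optimal).
#' @export
solve_lp <- function(obj, S, b = numeric(nrow(S)), lb, ub, maximize = TRUE,
                     tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  m <- nrow(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  if (any(!is.finite(lb)))
    stop("solve_lp requires finite lower bounds", call. = FALSE)
  if (any(lb > ub))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))

  # shift x = v - lb so x >= 0
  beq <- b - as.vector(S %*% lb)
  u <- ub - lb
  neg <- beq < 0
  S[neg, ] <- -S[neg, , drop = FALSE]
  beq[neg] <- -beq[neg]
  fin <- which(is.finite(u))
  nf <- length(fin)
  n_real <- n + nf
  nc <- n_real + m                      # x, bound slacks, artificials
  T <- matrix(0, m + nf, nc + 1L)
  T[seq_len(m), seq_len(n)] <- S
  if (m) T[cbind(seq_len(m), n_real + seq_len(m))] <- 1
  T[seq_len(m), nc + 1L] <- beq
  if (nf) {
    T[cbind(m + seq_len(nf), fin)] <- 1
    T[cbind(m + seq_len(nf), n + seq_len(nf))] <- 1
    T[m + seq_len(nf), nc + 1L] <- u[fin]
  }
  basis <- c(n_real + seq_len(m), n + seq_len(nf))

  # phase 1: minimize artificial sum
  cost1 <- c(rep(0, n_real), rep(1, m))
  res <- .simplex_iterate(T, basis, cost1, allowed = rep(TRUE, nc), tol = tol)
  T <- res$T
  basis <- res$basis
  art_val <- sum(T[basis > n_real, nc + 1L])
  if (art_val > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  # drive artificials out of the basis where possible
  for (r in which(basis > n_real)) {
    jj <- which(abs(T[r, seq_len(n_real)]) > tol)
    if (!length(jj)) next                     # redundant row, harmless
    j <- jj[1L]
    piv_row <- T[r, ] / T[r, j]
    T <- T - tcrossprod(T[, j], piv_row)
    T[r, ] <- piv_row
    basis[r] <- j
  }

  # phase 2
  sgn <- if (maximize) -1 else 1              # simplex minimizes
  cost2 <- c(sgn * obj, rep(0, nf), rep(0, m))
  allowed <- c(rep(TRUE, n_real), rep(FALSE, m))
  res <- .simplex_iterate(T, basis, cost2, allowed = allowed, tol = tol)
  if (res$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, solution = NULL))
  x <- numeric(nc)
  x[res$basis] <- res$T[, nc + 1L]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), solution = v)
}
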
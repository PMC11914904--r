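# Independent oracles used to validate the package implementations.
# These deliberately use brute-force enumeration, not the algorithms under
# test.

# LP oracle: exhaustive basic-feasible-solution (vertex) enumeration for
# max obj'v s.t. S v = 0, lb <= v <= ub with finite bounds. A vertex fixes
# n - rank(S) variables at a bound and solves for the rest.
lp_oracle <- function(obj, S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  best <- -Inf
  free_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (free in free_sets) {
    fixed <- setdiff(seq_len(n), free)
    Sf <- S[, free, drop = FALSE]
    if (length(free) && qr(Sf)$rank < length(free)) next
    for (mask in 0:(2^length(fixed) - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_along(fixed) - 1)) > 0
      vals <- ifelse(at_ub, ub[fixed], lb[fixed])
      v <- numeric(n)
      v[fixed] <- vals
      if (length(free)) {
        rhs <- -S[, fixed, drop = FALSE] %*% vals
        vf <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(vf)) next
        v[free] <- vf
      }
      if (max(abs(S %*% v)) < tol && all(v >= lb - tol) &&
          all(v <= ub + tol))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# random stoichiometric network with v = 0 always feasible (0 in [lb, ub])
random_network <- function(n_max = 8) {
  n <- sample(2:n_max, 1)
  m <- sample(1:5, 1)
  S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
  lb <- sample(c(-10, 0), n, replace = TRUE)
  ub <- sample(c(0, 5, 10), n, replace = TRUE)
  obj <- round(runif(n, -2, 2), 2)
  list(obj = obj, S = S, lb = lb, ub = ub)
}

# Local-alignment oracle: exhaustive enumeration of monotone matchings
# between positions of a and b (every gapped local alignment corresponds
# to one), scoring matched pairs by the substitution matrix and internal
# unmatched runs as affine gaps (cost open + ext * length). Empty
# alignment scores 0.
align_oracle <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av)
  nb <- length(bv)
  best <- 0
  rec <- function(i, j, sc) {
    best <<- max(best, sc)
    if (i < na && j < nb)
      for (i2 in (i + 1):na) for (j2 in (j + 1):nb) {
        gi <- i2 - i - 1
        gj <- j2 - j - 1
        gap <- (gi > 0) * (open + ext * gi) + (gj > 0) * (open + ext * gj)
        rec(i2, j2, sc + mat[av[i2], bv[j2]] - gap)
      }
  }
  for (i in seq_len(na)) for (j in seq_len(nb))
    rec(i, j, mat[av[i], bv[j]])
  best
}

# exact two-sided rank-sum p by enumerating all group labelings
rank_sum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  sets <- utils::combn(n, na, simplify = FALSE)
  us <- vapply(sets, u_of, 0)
  u_obs <- u_of(seq_len(na))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign flips
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    pos <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[pos])
  }, 0)
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# tau-b by explicit concordant/discordant pair counting
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  C <- 0
  D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1
    if (s < 0) D <- D + 1
  }
  tie <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tie(x)) * (n0 - tie(y)))
}

blosum62_x0 <- function() auxopep:::.blosum62_x0()
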
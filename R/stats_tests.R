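# Rank-based statistical layer: Kendall ordered correlation, Wilcoxon
# tests, BH-FDR, Spearman correlation matrix, PCoA, PERMANOVA, and the
# differential-peptidase screen. Exact small-sample p-values come from full
# enumeration; larger samples use tie-corrected normal approximations.

.test_result <- function(statistic, p_value, effect_label,
                         p_adjusted = NA_real_, note = NA_character_, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, effect_label = effect_label,
                 note = note, ...), class = "aux_test")
}

#' @export
print.aux_test <- function(x, ...) {
  cat("<test>", x$effect_label, "=", signif(x$statistic, 4),
      " p =", signif(x$p_value, 4),
      if (!is.na(x$p_adjusted)) paste(" p_adj =", signif(x$p_adjusted, 4)),
      if (!is.na(x$note)) paste(" [", x$note, "]"), "\n")
  invisible(x)
}

# Kendall S = C - D and the tie-corrected tau-b denominator
.kendall_s <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  sum(sx[lower.tri(sx)] * sy[lower.tri(sy)])
}

.kendall_denominator <- function(x, y) {
  n <- length(x)
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  sqrt((n0 - n1) * (n0 - n2))
}

#' Kendall rank correlation against an ordered factor (tau-b)
#'
#' Correlates a sample-level quantity (e.g. an auxotrophy abundance) with
#' the ordered intestinal region rank. Tau-b corrects for ties on both
#' sides. The two-sided p-value is exact (full permutation enumeration,
#' conditional on the observed tie structure) for n <= 8 and otherwise uses
#' the tie-corrected normal approximation.
#'
#' @param values Numeric vector.
#' @param region_ranks Integer vector of ordered ranks (e.g.
#'   [region_rank()]), same length, at least 2 distinct levels.
#' @return An `aux_test` with `statistic` = tau-b.
#' @export
kendall_ordered <- function(values, region_ranks) {
  n <- length(values)
  stopifnot(length(region_ranks) == n)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(region_ranks)) < 2)
    stop("region_ranks needs >= 2 distinct levels", call. = FALSE)
  if (length(unique(values)) == 1)
    return(.test_result(NA_real_, NA_real_, "tau",
                        note = "constant values; tau undefined"))
  S <- .kendall_s(values, region_ranks)
  denom <- .kendall_denominator(values, region_ranks)
  tau <- S / denom
  if (n <= 8) {
    perms <- .permutations(n)
    sx <- sign(outer(region_ranks, region_ranks, "-"))
    lower <- lower.tri(sx)
    sxl <- sx[lower]
    s_perm <- apply(perms, 1, function(idx) {
      sy <- sign(outer(values[idx], values[idx], "-"))
      sum(sxl * sy[lower])
    })
    p <- mean(abs(s_perm) >= abs(S) - 1e-9)
    return(.test_result(tau, p, "tau", method = "exact enumeration"))
  }
  # tie-corrected normal approximation (as in classical tau-b inference)
  xt <- as.numeric(table(values))
  yt <- as.numeric(table(region_ranks))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(xt * (xt - 1) * (2 * xt + 5))
  vu <- sum(yt * (yt - 1) * (2 * yt + 5))
  v1 <- sum(xt * (xt - 1)) * sum(yt * (yt - 1)) / (2 * n * (n - 1))
  v2 <- sum(xt * (xt - 1) * (xt - 2)) * sum(yt * (yt - 1) * (yt - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_s)
  .test_result(tau, 2 * stats::pnorm(-abs(z)), "tau",
               method = "normal approximation", z = z)
}

# all permutations of 1..n as a matrix (n! rows)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact by enumeration when the pooled size is <= 12 with no
#' ties, otherwise tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return An `aux_test` with `statistic` = Mann-Whitney U of group `a`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  exact <- (length(a) + length(b)) <= 12 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  .test_result(unname(wt$statistic), wt$p.value, "U",
               method = if (exact) "exact" else "normal approximation")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided, zero differences dropped first. Exact when n <= 12 without
#' tied absolute differences, otherwise normal approximation with
#' continuity correction. All-zero differences give p = 1 (degenerate,
#' noted).
#'
#' @param diffs Numeric vector of paired differences.
#' @return An `aux_test` with `statistic` = V (positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(diffs) {
  if (!length(diffs)) stop("empty differences", call. = FALSE)
  d <- diffs[diffs != 0]
  if (!length(d))
    return(.test_result(0, 1, "V", note = "all differences zero"))
  exact <- length(d) <= 12 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  .test_result(unname(wt$statistic), wt$p.value, "V",
               method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; input
#' order preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed and
#'   propagated).
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlation matrix between auxotrophy and peptidase abundances
#'
#' One rank correlation per (amino acid, peptidase) pair over the shared
#' samples; all p-values are adjusted jointly (BH) across the whole matrix.
#' Pairs with a constant column are flagged undefined (NA).
#'
#' @param aux_abund Matrix samples x amino acids.
#' @param pep_abund Matrix samples x peptidase ids.
#' @return Long-format data.frame: `amino_acid`, `merops_id`, `rho`, `p`,
#'   `p_adj`.
#' @export
spearman_matrix <- function(aux_abund, pep_abund) {
  shared <- intersect(rownames(aux_abund), rownames(pep_abund))
  if (length(shared) < 4)
    stop("need >= 4 shared samples", call. = FALSE)
  A <- aux_abund[shared, , drop = FALSE]
  P <- pep_abund[shared, , drop = FALSE]
  grid <- expand.grid(amino_acid = colnames(A), merops_id = colnames(P),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- A[, grid$amino_acid[k]]
    y <- P[, grid$merops_id[k]]
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_adj <- bh_fdr(out$p)
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are returned for positive-eigenvalue axes (descending);
#' negative eigenvalues are reported, not corrected.
#'
#' @param D Square symmetric distance matrix with zero diagonal (asymmetry
#'   beyond 1e-9 is an error).
#' @return List with `coordinates` (samples x axes) and `eigenvalues`
#'   (all, descending).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-9)
    stop("distance matrix must be square and symmetric (tol 1e-9)",
         call. = FALSE)
  if (max(abs(diag(D))) > 1e-9)
    stop("distance matrix must have zero diagonal", call. = FALSE)
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * C %*% (D^2) %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-9
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  if (ncol(coords))
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values)
}

# sums of squares directly from the squared distances
.permanova_f <- function(D2, groups) {
  n <- length(groups)
  ss_total <- sum(D2[lower.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  k <- length(unique(groups))
  f <- (ss_among / (k - 1)) / (ss_within / (n - k))
  c(f = f, r2 = ss_among / ss_total, ss_total = ss_total,
    ss_among = ss_among, ss_within = ss_within)
}

# distinct assignments of a multiset of labels to n positions
.label_arrangements <- function(groups) {
  labs <- sort(unique(groups))
  counts <- as.integer(table(factor(groups, levels = labs)))
  rec <- function(remaining, acc) {
    if (sum(remaining) == 0) return(list(acc))
    out <- list()
    for (i in seq_along(labs)) {
      if (remaining[i] == 0) next
      r2 <- remaining
      r2[i] <- r2[i] - 1L
      out <- c(out, rec(r2, c(acc, labs[i])))
    }
    out
  }
  rec(counts, character(0))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' is computed from among- and within-group sums of squared distances, and
#' its p-value from free permutations of the sample labels (one-way design,
#' no strata). When the number of distinct label arrangements is at most
#' 10,000 the null distribution is enumerated exactly; otherwise `n_perm`
#' random permutations are drawn and the add-one convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` keeps p strictly
#' positive (floor 0.001 at 999 permutations).
#'
#' @param D Square symmetric distance matrix.
#' @param groups Group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Seed for the permutation draw (RNG state is restored).
#' @return An `aux_test` with `statistic` = pseudo-F, plus `R2`, `method`,
#'   and the SS partition.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  stopifnot(nrow(D) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2))
    stop("each group needs >= 2 samples", call. = FALSE)
  D2 <- D^2
  obs <- .permanova_f(D2, groups)
  n <- length(groups)
  n_arr <- factorial(n) / prod(factorial(tab))
  if (n_arr <= 10000) {
    arr <- .label_arrangements(groups)
    f_perm <- vapply(arr, function(g) .permanova_f(D2, g)[["f"]], 0)
    p <- mean(f_perm >= obs[["f"]] - 1e-12)
    method <- sprintf("exact enumeration (%d arrangements)", length(arr))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    f_perm <- vapply(seq_len(n_perm), function(i)
      .permanova_f(D2, sample(groups))[["f"]], 0)
    p <- (1 + sum(f_perm >= obs[["f"]] - 1e-12)) / (1 + n_perm)
    method <- sprintf("%d random permutations", n_perm)
  }
  .test_result(obs[["f"]], p, "pseudo-F", R2 = obs[["r2"]],
               method = method, ss_total = obs[["ss_total"]],
               ss_among = obs[["ss_among"]], ss_within = obs[["ss_within"]])
}

#' Differential peptidase abundance screen between two sample groups
#'
#' Mirrors the region/group contrasts of peptidase profiles: peptidases are
#' first filtered by prevalence (median relative abundance of at least
#' `min_median_pct` percent in either group), then each retained peptidase
#' is tested (Wilcoxon signed-rank on matched samples when `paired`,
#' rank-sum otherwise), p-values are BH-adjusted (or used raw with
#' `adjust = "none"`), and peptidases with adjusted p below `alpha` are
#' flagged together with the direction of the median difference.
#'
#' @param abund_a,abund_b Matrices samples x peptidase ids (same columns;
#'   paired mode additionally requires matched sample identifiers).
#' @param paired Use the signed-rank test on per-sample differences.
#' @param min_median_pct Prevalence filter in percent of relative
#'   abundance (default 1).
#' @param alpha Significance threshold on the adjusted p (default 0.001).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return data.frame: `peptidase`, `median_a`, `median_b`, `statistic`,
#'   `p`, `p_adj`, `direction`, `significant`.
#' @export
differential_peptidase_screen <- function(abund_a, abund_b, paired = FALSE,
                                          min_median_pct = 1, alpha = 0.001,
                                          adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  if (!identical(colnames(abund_a), colnames(abund_b)))
    stop("groups must share the same peptidase columns", call. = FALSE)
  if (paired) {
    if (nrow(abund_a) != nrow(abund_b))
      stop("paired mode requires matched sample sets", call. = FALSE)
    if (!is.null(rownames(abund_a)) && !is.null(rownames(abund_b))) {
      if (!setequal(rownames(abund_a), rownames(abund_b)))
        stop("paired mode requires matched sample identifiers",
             call. = FALSE)
      abund_b <- abund_b[rownames(abund_a), , drop = FALSE]
    }
  }
  med_a <- apply(abund_a, 2, stats::median)
  med_b <- apply(abund_b, 2, stats::median)
  keep <- 100 * med_a >= min_median_pct | 100 * med_b >= min_median_pct
  if (!any(keep)) {
    message("no peptidase passes the median >= ", min_median_pct,
            "% prevalence filter")
    return(data.frame(peptidase = character(0), median_a = numeric(0),
                      median_b = numeric(0), statistic = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      direction = character(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  ids <- colnames(abund_a)[keep]
  tests <- lapply(ids, function(id) {
    if (paired) wilcoxon_signed_rank(abund_a[, id] - abund_b[, id])
    else wilcoxon_rank_sum(abund_a[, id], abund_b[, id])
  })
  p <- vapply(tests, `[[`, 0, "p_value")
  p_adj <- if (adjust == "BH") bh_fdr(p) else p
  md <- if (paired)
    vapply(ids, function(id)
      stats::median(abund_a[, id] - abund_b[, id]), 0)
  else med_a[ids] - med_b[ids]
  data.frame(
    peptidase = ids,
    median_a = unname(med_a[ids]), median_b = unname(med_b[ids]),
    statistic = vapply(tests, `[[`, 0, "statistic"),
    p = p, p_adj = p_adj,
    direction = ifelse(md > 0, "higher_in_a",
                       ifelse(md < 0, "higher_in_b", "none")),
    significant = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
}
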
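test_that("Kendall tau-b hits the monotone extremes", {
  up <- kendall_ordered(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(up$statistic, 1)
  dn <- kendall_ordered(c(6, 5, 4, 3, 2, 1), c(1, 2, 3, 4, 5, 6))
  expect_equal(dn$statistic, -1)
  expect_lt(dn$p_value, 0.05)
})

test_that("tau-b with tied ranks equals the pair-enumeration oracle", {
  x <- c(5, 4, 3, 3, 2, 1)
  rk <- c(1, 1, 2, 2, 3, 3)
  t <- kendall_ordered(x, rk)
  expect_equal(t$statistic, kendall_tau_oracle(x, rk), tolerance = 1e-12)
  # and equals base R's tie-corrected tau
  expect_equal(t$statistic, unname(cor(x, rk, method = "kendall")),
               tolerance = 1e-12)
})

test_that("large-sample Kendall inference matches cor.test", {
  set.seed(409)
  x <- rnorm(25)
  rk <- sample(1:4, 25, replace = TRUE)
  t <- kendall_ordered(x, rk)
  ct <- suppressWarnings(cor.test(x, rk, method = "kendall",
                                  exact = FALSE))
  expect_equal(t$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(t$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("degenerate Kendall inputs are flagged or rejected", {
  expect_error(kendall_ordered(c(1, 2), c(1, 2)), "at least 3")
  expect_error(kendall_ordered(1:5, rep(2, 5)), "distinct")
  flat <- kendall_ordered(rep(1, 5), c(1, 1, 2, 2, 3))
  expect_true(is.na(flat$statistic))
  expect_match(flat$note, "constant")
})

test_that("rank-sum p-values match full enumeration", {
  t <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$p_value, 0.1)           # 2/20 labelings as extreme
  expect_equal(t$p_value, rank_sum_oracle(c(1, 2, 3), c(4, 5, 6)))

  set.seed(410)
  for (i in 1:10) {
    a <- round(rnorm(sample(2:4, 1)), 3)
    b <- round(rnorm(sample(2:4, 1)), 3)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, rank_sum_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum is symmetric and degenerate-safe", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(0.4, 5.5, 2.9)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("signed-rank p-values match sign-flip enumeration", {
  t <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(t$p_value, 2 / 32)        # all-positive, 2^5 flips
  expect_equal(t$p_value, signed_rank_oracle(c(1, 2, 3, 4, 5)))

  set.seed(411)
  for (i in 1:10) {
    d <- round(rnorm(sample(3:8, 1)), 3)
    expect_equal(wilcoxon_signed_rank(d)$p_value, signed_rank_oracle(d),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(-d)$p_value,
                 wilcoxon_signed_rank(d)$p_value)
  }
})

test_that("signed-rank handles symmetric and all-zero differences", {
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p_value, 1)
  z <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(z$p_value, 1)
  expect_match(z$note, "zero")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(412)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))             # never below raw
  expect_true(all(adj <= 1))
  ord <- sample(50)
  expect_equal(bh_fdr(p[ord]), adj[ord]) # permutation-equivariant
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman matrix adjusts jointly and flags constant columns", {
  set.seed(413)
  n <- 12
  A <- cbind(His = rnorm(n), Leu = rnorm(n), Trp = rep(0.5, n))
  P <- cbind(`S09.075` = rnorm(n), `M16.001` = rnorm(n))
  P[, 1] <- P[, 1] - 2 * A[, "His"]       # strong negative association
  rownames(A) <- rownames(P) <- paste0("s", 1:n)
  res <- spearman_matrix(A, P)
  expect_equal(nrow(res), 6)
  # constant column flagged NA
  expect_true(all(is.na(res$rho[res$amino_acid == "Trp"])))
  # matches cor.test cell-wise
  ct <- suppressWarnings(cor.test(A[, "His"], P[, 1], method = "spearman",
                                  exact = FALSE))
  row <- res[res$amino_acid == "His" & res$merops_id == "S09.075", ]
  expect_equal(row$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_lt(row$rho, 0)
  # joint BH over the 5 defined cells
  expect_equal(res$p_adj[!is.na(res$p)], bh_fdr(res$p[!is.na(res$p)]))
  expect_error(spearman_matrix(A[1:3, ], P[1:3, ]), ">= 4")
})

test_that("PCoA embeds Euclidean-realizable distances exactly", {
  # three collinear points at 0, 1, 2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  res <- pcoa(D)
  expect_equal(sum(res$eigenvalues > 1e-9), 1)
  emb <- as.matrix(dist(res$coordinates))
  expect_equal(unname(emb), unname(D), tolerance = 1e-9)

  # trace identity for Euclidean input: sum of positive eigenvalues equals
  # the total centered sum of squares
  set.seed(414)
  X <- matrix(rnorm(30), 10, 3)
  D2 <- as.matrix(dist(X))
  res2 <- pcoa(D2)
  Xc <- scale(X, scale = FALSE)
  expect_equal(sum(res2$eigenvalues[res2$eigenvalues > 0]), sum(Xc^2),
               tolerance = 1e-9)
  # agrees with classical MDS up to sign
  cm <- cmdscale(D2, k = 2)
  expect_equal(abs(res2$coordinates[, 1:2]), abs(cm), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_equal(pcoa(matrix(0, 4, 4))$eigenvalues, rep(0, 4))
  Dasym <- D
  Dasym[1, 2] <- 1.5
  expect_error(pcoa(Dasym), "symmetric")
  expect_error(pcoa(D + diag(3)), "diagonal")
})

test_that("PERMANOVA separates planted groups and partitions SS", {
  # two tight clusters: R2 = 1 and minimal attainable p
  X <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  D <- as.matrix(dist(X))
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(D, g)
  expect_equal(res$R2, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 2 / 20)       # 20 arrangements, 2 perfect
  expect_equal(res$ss_among + res$ss_within, res$ss_total,
               tolerance = 1e-9)
})

test_that("exact enumeration agrees with Monte-Carlo permutations", {
  set.seed(415)
  X <- matrix(rnorm(12), 6, 2)
  X[4:6, ] <- X[4:6, ] + 1.2
  D <- as.matrix(dist(X))
  g <- rep(c("a", "b"), each = 3)
  exact <- permanova(D, g)
  expect_match(exact$method, "exact")
  # the Monte-Carlo path needs a larger label multiset: n = 12, 4 groups
  X2 <- rbind(X, X + 0.3)
  D2 <- as.matrix(dist(X2))
  g2 <- rep(c("a", "b", "c", "d"), each = 3)
  mc2 <- permanova(D2, g2, n_perm = 999, seed = 7)
  expect_match(mc2$method, "permutations")
  expect_true(mc2$p_value >= 1 / 1000)
  # reproducible under a fixed seed
  expect_identical(mc2$p_value,
                   permanova(D2, g2, n_perm = 999, seed = 7)$p_value)
  expect_true(exact$R2 >= 0 && exact$R2 <= 1)
})

test_that("PERMANOVA matches vegan's pseudo-F and R2", {
  skip_if_not_installed("vegan")
  set.seed(416)
  X <- matrix(abs(rnorm(40)), 10, 4)
  g <- rep(c("a", "b"), each = 5)
  D <- as.matrix(vegan::vegdist(X, method = "bray"))
  ours <- permanova(D, g, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(D) ~ g,
                        permutations = 999)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-9)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-9)
})

test_that("PERMANOVA rejects degenerate designs", {
  D <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  expect_error(permanova(D, c("a", "a", "a", "a")), ">= 2 groups")
  expect_error(permanova(D, c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("the differential screen filters by prevalence then tests", {
  set.seed(417)
  n <- 20
  # pep1: planted constant shift (paired); pep2: null; pep3: too rare
  base <- matrix(abs(rnorm(3 * n, mean = 0.05, sd = 0.01)), n, 3,
                 dimnames = list(paste0("s", 1:n),
                                 c("S09.075", "M16.001", "C01.001")))
  A <- base
  A[, "S09.075"] <- A[, "S09.075"] + 0.05
  A[, "C01.001"] <- 0.004                 # median 0.4% in both groups
  B <- base
  B[, "C01.001"] <- 0.005
  res <- differential_peptidase_screen(A, B, paired = TRUE)
  expect_setequal(res$peptidase, c("S09.075", "M16.001"))  # C01 filtered
  s09 <- res[res$peptidase == "S09.075", ]
  expect_true(s09$significant)
  expect_equal(s09$direction, "higher_in_a")
  expect_false(res$significant[res$peptidase == "M16.001"])

  # a peptidase above 1% in only one group is still tested
  A2 <- cbind(`S01.001` = rep(0.02, 6))
  B2 <- cbind(`S01.001` = rep(0.001, 6))
  rownames(A2) <- rownames(B2) <- paste0("x", 1:6)
  res2 <- differential_peptidase_screen(A2, B2, paired = FALSE,
                                        alpha = 0.05)
  expect_equal(res2$peptidase, "S01.001")

  # nothing passing the filter yields an empty, well-formed table
  expect_message(
    res3 <- differential_peptidase_screen(A2 * 0.01, B2 * 0.01),
    "prevalence")
  expect_equal(nrow(res3), 0)
})

test_that("screen in raw-p mode uses unadjusted thresholds", {
  set.seed(418)
  A <- matrix(runif(40, 0.01, 0.2), 10, 4,
              dimnames = list(NULL, paste0("S09.00", 1:4)))
  B <- matrix(runif(40, 0.01, 0.2), 10, 4,
              dimnames = list(NULL, paste0("S09.00", 1:4)))
  raw <- differential_peptidase_screen(A, B, adjust = "none",
                                       alpha = 0.05)
  expect_equal(raw$p, raw$p_adj)
})
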
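test_that("self-alignment scores the diagonal BLOSUM62 sum", {
  q <- "HEAGAWGHEE"
  res <- local_align_protein(q, q)
  m <- blosum62_x0()
  chars <- strsplit(q, "")[[1]]
  expect_equal(res$raw_score, sum(m[cbind(chars, chars)]))
  expect_equal(res$query_span, c(1, 10))
  expect_equal(res$target_span, c(1, 10))
})

test_that("dissimilar sequences floor at score 0 with empty spans", {
  res <- local_align_protein("WWWW", "PPPP")   # W/P = -4 everywhere
  expect_equal(res$raw_score, 0)
  expect_null(res$query_span)
  expect_null(res$target_span)
})

test_that("an interior mismatch costs exactly self minus substitution", {
  q <- "KKKKKWKKKKK"
  t <- "KKKKKFKKKKK"     # W->F: self 11, substitution 1
  m <- blosum62_x0()
  self <- local_align_protein(q, q)$raw_score
  res <- local_align_protein(q, t)
  expect_equal(self - res$raw_score, m["W", "W"] - m["W", "F"])
})

test_that("X residues are tolerated and scored zero", {
  res <- local_align_protein("KKKXKKK", "KKKWKKK")
  expect_equal(res$raw_score, 6 * blosum62_x0()["K", "K"])
  expect_error(local_align_protein("KKKBZK", "KKK"), "alphabet")
  expect_error(local_align_protein("", "KKK"), "empty")
})

test_that("DP alignment equals the exhaustive matching-enumeration oracle", {
  set.seed(406)
  m <- blosum62_x0()
  for (i in 1:25) {
    a <- random_protein(sample(4:9, 1))
    b <- random_protein(sample(4:9, 1))
    for (gp in list(c(11, 1), c(2, 1))) {
      got <- local_align_protein(a, b, gap_open = gp[1],
                                 gap_extend = gp[2])$raw_score
      expect_equal(got, align_oracle(a, b, m, gp[1], gp[2]),
                   info = paste(a, b, gp[1]))
    }
  }
})

test_that("Karlin-Altschul statistics follow the stated formulas", {
  ka <- karlin_altschul(300, m = 200, n = 1e5)
  expect_equal(ka$bitscore, (0.267 * 300 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(ka$bitscore, 120.168, tolerance = 1e-3)
  expect_equal(ka$evalue, 200 * 1e5 * 2^(-ka$bitscore), tolerance = 1e-12)

  ka0 <- karlin_altschul(0, 10, 10)
  expect_equal(ka0$bitscore, -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(ka0$bitscore, 4.608, tolerance = 1e-3)

  # strictly monotone in the raw score
  expect_gt(karlin_altschul(600, 10, 10)$bitscore,
            karlin_altschul(300, 10, 10)$bitscore)
  expect_error(karlin_altschul(-1, 10, 10), ">= 0")
  expect_error(karlin_altschul(10, 0, 10), "positive")
})

test_that("merops id format is enforced, including letter member parts", {
  expect_error(scan_db(data.frame(merops_id = "S9.075",
                                  sequence = "KKKK",
                                  unit_start = 1, unit_end = 4)),
               "malformed")
  ok <- scan_db(data.frame(merops_id = c("S09.075", "S09.A41"),
                           sequence = c("KKKK", "RRRR"),
                           unit_start = 1, unit_end = 4))
  expect_s3_class(ok, "scan_db")
  expect_error(scan_db(data.frame(merops_id = "S09.075",
                                  sequence = "KKKK",
                                  unit_start = 1, unit_end = 9)),
               "unit span")
})

test_that("planted domains are retained; truncated units and decoys are not", {
  fx <- peptidase_fixture()
  hits <- call_peptidases(fx$catalog, fx$db)
  expect_equal(hits$protein_id, "G1_full")
  expect_equal(hits$merops_id, "S09.075")
  expect_equal(hits$family, "S09")
  expect_equal(hits$unit_coverage, 100)
  expect_gt(hits$bitscore, 100)
  expect_lt(hits$evalue, 0.01)
})

test_that("each retention filter is independently decisive at its boundary", {
  fx <- peptidase_fixture()
  hits <- call_peptidases(fx$catalog, fx$db)
  b0 <- hits$bitscore[1]

  # bitscore filter is strict: a hit at exactly the threshold is rejected
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    min_bitscore = b0)), 0)
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    min_bitscore = b0 - 0.5)), 1)

  # unit coverage is inclusive at the threshold
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    min_unit_cov = 100)), 1)
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    min_unit_cov = 100 + 1e-9)), 0)

  # query coverage is strict
  q0 <- hits$query_coverage[1]
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    min_query_cov = q0)), 0)

  # e-value filter is strict
  e0 <- hits$evalue[1]
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    max_evalue = e0)), 0)
  expect_equal(nrow(call_peptidases(fx$catalog, fx$db,
                                    max_evalue = e0 * 2)), 1)
})

test_that("tightening any threshold never adds hits", {
  set.seed(408)
  b <- make_catalog(6, aux_rate_per_aa = 0, pep_gene_rate = 0.6, seed = 17,
                    domain_mutation_rate = 0.05)
  base <- call_peptidases(b$catalog, b$scan_db, min_bitscore = 50,
                          min_unit_cov = 80, min_query_cov = 70)
  key <- function(h) paste(h$protein_id, h$merops_id)
  loose <- list(catalog = b$catalog, db = b$scan_db, min_bitscore = 50,
                min_unit_cov = 80, min_query_cov = 70)
  for (args in list(list(min_bitscore = 100),
                    list(min_unit_cov = 95),
                    list(min_query_cov = 85),
                    list(max_evalue = 1e-30))) {
    h <- do.call(call_peptidases, utils::modifyList(loose, args))
    expect_true(all(key(h) %in% key(base)))
  }
})

test_that("the toy signal-peptide rule fires on its definition", {
  pos <- paste0("MKR", strrep("L", 8), random_protein(40))
  neg_charge <- paste0("MSS", strrep("L", 8), random_protein(40))
  neg_run <- paste0("MKR", "LALA", random_protein(40))
  expect_true(predict_signal_peptide(pos))
  expect_false(predict_signal_peptide(neg_charge))
  expect_false(predict_signal_peptide(neg_run))
})

test_that("extracellular aggregation distinguishes copies and distinct ids", {
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4"),
    genome_id = c("G1", "G1", "G1", "G2"),
    merops_id = c("S09.075", "S09.075", "M16.001", "C01.001"),
    family = c("S09", "S09", "M16", "C01"),
    raw_score = 500, bitscore = 150, evalue = 0,
    query_coverage = 100, unit_coverage = 100)
  sig <- c(p1 = TRUE, p2 = TRUE, p3 = FALSE, p4 = FALSE)
  prof <- flag_extracellular(hits, sig, genomes = c("G1", "G2", "G3"))
  # two signal-positive copies of the same id: copies 2, distinct 1
  expect_equal(unname(prof$copies[c("G1", "G2", "G3")]), c(2L, 0L, 0L))
  expect_equal(unname(prof$distinct["G1"]), 1L)
  expect_equal(prof$merops_ids$G1, "S09.075")
  # zero-count genomes remain present
  expect_setequal(names(prof$copies), c("G1", "G2", "G3"))

  # proteins missing from the table are treated signal-negative
  expect_message(prof2 <- flag_extracellular(hits, sig[c("p1", "p2")]),
                 "missing")
  expect_equal(unname(prof2$copies["G1"]), 2L)
})
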
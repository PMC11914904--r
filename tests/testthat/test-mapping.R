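# 16S-like references built from a fixed random backbone; ASVs are exact
# or controlled-mismatch windows so identities are known by construction.

make_mapping_fixture <- function() {
  set.seed(404)
  backbone <- random_dna(300)
  far <- mutate_at(backbone, seq(5, 300, by = 6))   # ~17% diverged
  list(backbone = backbone, far = far,
       window = substr(backbone, 51, 250))
}

test_that("identity and coverage are exact for planted windows", {
  fx <- make_mapping_fixture()
  cat <- catalog_from_ssu(list(A = fx$backbone, B = fx$far))
  asvs <- asv_table(
    c(exact = fx$window,
      mm6 = mutate_at(fx$window, c(10, 40, 80, 120, 160, 190)),   # 97.0%
      mm8 = mutate_at(fx$window, c(10, 40, 80, 120, 160, 190, 60, 140))),
    matrix(1, 3, 1, dimnames = list(c("exact", "mm6", "mm8"), "s1")))
  hits <- map_asvs(asvs, cat)
  expect_setequal(hits$asv_id, c("exact", "mm6"))     # 96% excluded
  expect_equal(hits$genome_id, c("A", "A"))
  expect_equal(hits$identity[hits$asv_id == "exact"], 100)
  expect_equal(hits$identity[hits$asv_id == "mm6"], 97)  # boundary kept
  expect_equal(hits$query_coverage, c(100, 100))
})

test_that("reverse-complement ASVs map identically", {
  fx <- make_mapping_fixture()
  cat <- catalog_from_ssu(list(A = fx$backbone))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$window)))
  asvs <- asv_table(c(fwd = fx$window, rev = rc),
                    matrix(1, 2, 1,
                           dimnames = list(c("fwd", "rev"), "s1")))
  hits <- map_asvs(asvs, cat)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$identity, c(100, 100))
})

test_that("only maximum-identity ties are retained", {
  fx <- make_mapping_fixture()
  # A and B identical; C one extra mismatch inside the ASV window
  cat <- catalog_from_ssu(list(A = fx$backbone, B = fx$backbone,
                               C = mutate_at(fx$backbone, 100)))
  asv <- mutate_at(fx$window, c(10, 40, 80, 120))    # 98% to A/B, 97.5% to C
  asvs <- asv_table(c(tied = asv),
                    matrix(1, 1, 1, dimnames = list("tied", "s1")))
  hits <- map_asvs(asvs, cat)
  expect_setequal(hits$genome_id, c("A", "B"))
  expect_equal(unique(hits$identity), 98)
})

test_that("a genome's identity is the max over its multiple 16S genes", {
  fx <- make_mapping_fixture()
  cat <- reference_catalog(list(
    A = list(ssu = c(fx$far, fx$backbone), proteins = character(0),
             completeness = 100)))
  asvs <- asv_table(c(x = fx$window),
                    matrix(1, 1, 1, dimnames = list("x", "s1")))
  hits <- map_asvs(asvs, cat)
  expect_equal(hits$identity, 100)
})

test_that("raising min_identity never adds hits", {
  set.seed(405)
  backbone <- random_dna(300)
  cat <- catalog_from_ssu(list(A = backbone,
                               B = mutate_at(backbone, seq(3, 300, 9))))
  seqs <- sapply(1:6, function(i)
    mutate_at(substr(backbone, 51, 250), sample(200, sample(0:15, 1))))
  names(seqs) <- paste0("a", 1:6)
  asvs <- asv_table(seqs, matrix(1, 6, 1,
                                 dimnames = list(names(seqs), "s1")))
  prev <- NULL
  for (thr in c(90, 94, 97, 99, 100)) {
    h <- map_asvs(asvs, cat, min_identity = thr)
    key <- paste(h$asv_id, h$genome_id)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("non-IUPAC ASV characters are rejected", {
  fx <- make_mapping_fixture()
  cat <- catalog_from_ssu(list(A = fx$backbone))
  asvs <- asv_table(c(bad = "ACGTQACGT"),
                    matrix(1, 1, 1, dimnames = list("bad", "s1")))
  expect_error(map_asvs(asvs, cat), "non-IUPAC")
})

test_that("abundances follow the equal-split tie rule", {
  counts <- matrix(c(60L, 40L), 2, 1,
                   dimnames = list(c("ASV1", "ASV2"), "s1"))
  asvs <- asv_table(c(ASV1 = "ACGT", ASV2 = "TGCA"), counts)

  hits <- data.frame(asv_id = c("ASV1", "ASV2"),
                     genome_id = c("A", "B"),
                     identity = 100, query_coverage = 100)
  sa <- assign_abundance(asvs, hits)
  expect_equal(sa$abund["s1", c("A", "B")], c(A = 0.6, B = 0.4))

  # tie: ASV1 (50) split over {A, B}, ASV2 (50) to A -> A 0.75, B 0.25
  counts2 <- matrix(c(50L, 50L), 2, 1,
                    dimnames = list(c("ASV1", "ASV2"), "s1"))
  asvs2 <- asv_table(c(ASV1 = "ACGT", ASV2 = "TGCA"), counts2)
  hits2 <- data.frame(asv_id = c("ASV1", "ASV1", "ASV2"),
                      genome_id = c("A", "B", "A"),
                      identity = 100, query_coverage = 100)
  sa2 <- assign_abundance(asvs2, hits2)
  expect_equal(sa2$abund["s1", c("A", "B")], c(A = 0.75, B = 0.25))

  # drop_ambiguous: the tied ASV is discarded entirely
  sa3 <- assign_abundance(asvs2, hits2, ties = "drop_ambiguous")
  expect_equal(sa3$abund["s1", "A"], 1)
  expect_false("B" %in% colnames(sa3$abund))
})

test_that("rows sum to one and unmapped samples are flagged", {
  counts <- matrix(c(5L, 3L, 0L, 0L), 2, 2,
                   dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
  asvs <- asv_table(c(ASV1 = "ACGT", ASV2 = "TGCA"), counts)
  hits <- data.frame(asv_id = c("ASV1", "ASV2"),
                     genome_id = c("A", "B"),
                     identity = 100, query_coverage = 100)
  expect_message(sa <- assign_abundance(asvs, hits), "zero mapped")
  expect_equal(sa$unmapped_samples, "s2")
  expect_equal(rownames(sa$abund), "s1")
  expect_equal(sum(sa$abund), 1, tolerance = 1e-12)

  # hits referring to unknown ASVs are an input error
  bad <- data.frame(asv_id = "ghost", genome_id = "A",
                    identity = 100, query_coverage = 100)
  expect_error(assign_abundance(asvs, bad), "absent")
})

test_that("metadata regions are validated and attached", {
  counts <- matrix(4L, 1, 1, dimnames = list("ASV1", "s1"))
  asvs <- asv_table(c(ASV1 = "ACGT"), counts)
  hits <- data.frame(asv_id = "ASV1", genome_id = "A",
                     identity = 100, query_coverage = 100)
  md <- data.frame(sample_id = "s1", region = "duodenum", group = "SIBO")
  sa <- assign_abundance(asvs, hits, md)
  expect_equal(sa$metadata$region, "duodenum")
  md_bad <- data.frame(sample_id = "s1", region = "stomach", group = NA)
  expect_error(assign_abundance(asvs, hits, md_bad), "region")
})
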
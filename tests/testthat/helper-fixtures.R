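# Small in-code fixtures shared across test files.

# one-substrate chain: uptake -> transport -> biomass, yield 1
chain_model <- function(uptake_ub = 1000) {
  metabolic_model(
    "chain",
    metabolites = data.frame(
      id = c("S_e", "S_c"),
      compartment = c("extracellular", "cytosol")),
    reactions = list(
      list(id = "EX_S", stoichiometry = c(S_e = -1),
           lower_bound = -1000, upper_bound = uptake_ub),
      list(id = "T_S", stoichiometry = c(S_e = -1, S_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "biomass", stoichiometry = c(S_c = -1),
           lower_bound = 0, upper_bound = 1000)),
    biomass_reaction_id = "biomass",
    exchange_map = c(S_e = "EX_S"))
}

# biomass requires a metabolite nothing produces
orphan_model <- function() {
  metabolic_model(
    "orphan",
    metabolites = data.frame(
      id = c("S_e", "S_c", "X_c"),
      compartment = c("extracellular", "cytosol", "cytosol")),
    reactions = list(
      list(id = "EX_S", stoichiometry = c(S_e = -1),
           lower_bound = -1000, upper_bound = 1000),
      list(id = "T_S", stoichiometry = c(S_e = -1, S_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "biomass", stoichiometry = c(S_c = -1, X_c = -1),
           lower_bound = 0, upper_bound = 1000)),
    biomass_reaction_id = "biomass",
    exchange_map = c(S_e = "EX_S"))
}

# catalog of hand-built genomes from explicit 16S sequences
catalog_from_ssu <- function(ssu_list, completeness = 100) {
  reference_catalog(lapply(ssu_list, function(s)
    list(ssu = s, proteins = character(0), completeness = completeness)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n)
  paste(sample(auxopep:::.protein_alphabet(), n, replace = TRUE),
        collapse = "")

# plant n_mut substitutions into a sequence
mutate_at <- function(seq, pos, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(alphabet, ch[p])[1]
  paste(ch, collapse = "")
}

# A planted-domain fixture: one genome whose proteome contains an exact
# copy of the scan sequence (positive), a copy missing part of the unit
# (coverage failure), and a scrambled copy (decoy).
peptidase_fixture <- function() {
  set.seed(407)
  scan_seq <- random_protein(200)
  db <- scan_db(data.frame(merops_id = "S09.075", sequence = scan_seq,
                           unit_start = 11L, unit_end = 190L))
  full <- paste0(random_protein(30), scan_seq, random_protein(30))
  # first 172 residues: query coverage 86% (> 85) but unit coverage
  # (172 - 10) / 180 = 90% (< 95)
  truncated <- paste0(random_protein(30), substr(scan_seq, 1, 172))
  decoy <- paste(sample(strsplit(scan_seq, "")[[1]]), collapse = "")
  cat <- reference_catalog(list(
    G1 = list(ssu = "ACGT",
              proteins = c(G1_full = full, G1_trunc = truncated,
                           G1_decoy = decoy),
              completeness = 100)))
  list(db = db, catalog = cat)
}

# minimal auxotrophy profile object for community-metric tests
manual_profile <- function(calls_list, growth = NULL) {
  aas <- amino_acids()
  calls <- t(vapply(calls_list, function(aux) aas %in% aux,
                    logical(length(aas))))
  dimnames(calls) <- list(names(calls_list), aas)
  structure(list(
    calls = calls,
    n_auxotrophies = setNames(rowSums(calls), names(calls_list)),
    growth_full = if (is.null(growth))
      setNames(rep(1, length(calls_list)), names(calls_list)) else growth,
    excluded = data.frame()), class = "auxotrophy_profile")
}

# minimal peptidase profile: named list genome -> character vector of
# merops ids (duplicates = extra gene copies)
manual_pep_profile <- function(genes) {
  structure(list(
    copies = setNames(lengths(genes), names(genes)),
    distinct = setNames(vapply(genes, function(g) length(unique(g)), 0L),
                        names(genes)),
    merops_ids = lapply(genes, unique),
    hits = data.frame()), class = "peptidase_profile")
}
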
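# Synthetic study generator: a reference catalog with planted auxotrophies
# (model knockouts), planted secreted peptidase genes, 16S-derived ASVs at
# controlled identities, and Dirichlet-multinomial communities with
# region/group abundance tilts. Everything is a pure function of
# (parameters, seed); the planted truth is returned alongside the data so
# every pipeline stage can be scored.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

.random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute exactly n_mut positions (chosen without replacement) with a
# different letter
.mutate_seq <- function(seq, n_mut, alphabet) {
  if (n_mut == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos)
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Template genome-scale model with complete amino-acid biosynthesis
#'
#' A minimal prototrophic model: a carbon source is imported and converted
#' to a universal precursor; every amino acid has a biosynthesis reaction
#' (precursor -> cytosolic amino acid) plus an exchange and a transport
#' reaction; biomass consumes the precursor and all 20 cytosolic amino
#' acids. The model grows both on the full medium and on carbon alone, so
#' auxotrophies arise only by knocking out biosynthesis reactions. Reaction
#' count: 3 shared + 3 per amino acid + biomass = 64.
#'
#' @param aa_codes The amino acids to include (default all 20).
#' @return A [metabolic_model()] with completeness 100.
#' @export
make_template_model <- function(aa_codes = amino_acids()) {
  mets <- data.frame(
    id = c("carbon_e", "carbon_c", "precursor_c",
           paste0("aa_", aa_codes, "_e"), paste0("aa_", aa_codes, "_c")),
    compartment = c("extracellular", "cytosol", "cytosol",
                    rep("extracellular", length(aa_codes)),
                    rep("cytosol", length(aa_codes))),
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_carbon", stoichiometry = c(carbon_e = -1),
         lower_bound = -1000, upper_bound = 1000),
    list(id = "T_carbon", stoichiometry = c(carbon_e = -1, carbon_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "R_precursor",
         stoichiometry = c(carbon_c = -1, precursor_c = 1),
         lower_bound = 0, upper_bound = 1000))
  for (aa in aa_codes) {
    e <- paste0("aa_", aa, "_e")
    cy <- paste0("aa_", aa, "_c")
    rxns <- c(rxns, list(
      list(id = paste0("EX_aa_", aa),
           stoichiometry = stats::setNames(-1, e),
           lower_bound = -1000, upper_bound = 1000),
      list(id = paste0("T_aa_", aa),
           stoichiometry = stats::setNames(c(-1, 1), c(e, cy)),
           lower_bound = 0, upper_bound = 1000),
      list(id = paste0("BS_", aa),
           stoichiometry = stats::setNames(c(-1, 1), c("precursor_c", cy)),
           lower_bound = 0, upper_bound = 1000)))
  }
  biomass_st <- stats::setNames(
    rep(-1, length(aa_codes) + 1),
    c("precursor_c", paste0("aa_", aa_codes, "_c")))
  rxns <- c(rxns, list(list(id = "biomass", stoichiometry = biomass_st,
                            lower_bound = 0, upper_bound = 1000)))
  exch <- stats::setNames(c("EX_carbon", paste0("EX_aa_", aa_codes)),
                          c("carbon_e", paste0("aa_", aa_codes, "_e")))
  metabolic_model("template", mets, rxns, "biomass", exch,
                  completeness = 100)
}

#' Full synthetic growth medium
#'
#' Carbon source plus all 20 free amino acids, each at uptake rate 10
#' (abstract flux units).
#'
#' @param uptake Maximum uptake rate applied to every component.
#' @return A [growth_medium()].
#' @export
template_medium <- function(uptake = 10) {
  growth_medium(stats::setNames(
    rep(uptake, 21), c("carbon_e", paste0("aa_", amino_acids(), "_e"))))
}

#' Delete amino-acid biosynthesis reactions from a model
#'
#' Removing the biosynthesis reaction of an amino acid makes the template
#' model auxotrophic for exactly that amino acid.
#'
#' @param model A model built by [make_template_model()].
#' @param aas Character vector of amino-acid codes to knock out.
#' @return The reduced [metabolic_model()].
#' @export
knockout <- function(model, aas) {
  if (!length(aas)) return(model)
  unknown <- setdiff(aas, amino_acids())
  if (length(unknown))
    stop("unknown amino acid(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  drop_ids <- paste0("BS_", aas)
  keep <- vapply(model$reactions,
                 function(r) !r$id %in% drop_ids, TRUE)
  model$reactions <- model$reactions[keep]
  validate_model(model)
  model
}

# signal-peptide prefix satisfying the toy rule (25 residues)
.signal_prefix <- function() {
  paste0("M", paste(sample(c("K", "R"), 3, replace = TRUE), collapse = ""),
         paste(sample(c("L", "A", "V", "I", "F"), 10, replace = TRUE),
               collapse = ""),
         .random_seq(11, setdiff(.protein_alphabet(), c("L", "A", "V",
                                                        "I", "F"))))
}

#' Generate a synthetic reference catalog with planted ground truth
#'
#' Per genome: a 16S gene mutated from a shared 300-nt ancestor (about 95%
#' identity to the ancestor, so genomes stay mutually well below the 97%
#' ASV mapping threshold); a proteome of random background proteins plus
#' planted scan-database domains behind a signal-peptide prefix; one
#' scrambled (decoy) domain copy; a knockout metabolic model matching the
#' drawn auxotrophy set; completeness drawn from \{80, 90, 100\} so the 85%
#' screening gate is exercised. Deterministic under `seed`.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param aux_rate_per_aa Probability that a genome is auxotrophic for each
#'   amino acid (independent draws).
#' @param pep_gene_rate Probability that a genome carries a secreted copy
#'   of each scan-database entry.
#' @param seed Integer seed.
#' @param domain_mutation_rate Per-residue substitution rate applied to
#'   planted domain copies (default 0.01).
#' @param n_scan Number of scan-database entries.
#' @return A `synthetic_bundle`: list with `catalog`
#'   ([reference_catalog()]), `models`, `scan_db`, `signal_table`,
#'   `medium`, and `truth` (planted auxotrophies, secreted peptidase copies
#'   per genome, decoy proteins, completeness).
#' @export
make_catalog <- function(n_genomes, aux_rate_per_aa = 0.15,
                         pep_gene_rate = 0.3, seed = 1,
                         domain_mutation_rate = 0.01, n_scan = 8) {
  if (n_genomes < 2) stop("need at least 2 genomes", call. = FALSE)
  stopifnot(aux_rate_per_aa >= 0, aux_rate_per_aa <= 1,
            pep_gene_rate >= 0, pep_gene_rate <= 1)
  .with_seed(seed, {
    dna <- c("A", "C", "G", "T")
    aa_alpha <- .protein_alphabet()
    aas <- amino_acids()
    gids <- sprintf("G%03d", seq_len(n_genomes))
    ancestor <- .random_seq(300, dna)

    fams <- c("S09", "M16", "C01", "S01", "T03", "M23", "S11", "C40",
              "S12", "C82")
    scan <- data.frame(
      merops_id = paste0(fams[(seq_len(n_scan) - 1) %% length(fams) + 1],
                         sprintf(".%03d", seq_len(n_scan))),
      sequence = vapply(seq_len(n_scan), function(i)
        .random_seq(sample(160:220, 1), aa_alpha), ""),
      stringsAsFactors = FALSE)
    scan$unit_start <- 11L
    scan$unit_end <- nchar(scan$sequence) - 10L
    scan <- scan_db(scan)

    template <- make_template_model()
    genomes <- list()
    models <- list()
    truth_aux <- list()
    truth_pep <- list()
    truth_decoy <- list()
    completeness <- stats::setNames(
      sample(c(80, 90, 100), n_genomes, replace = TRUE), gids)
    for (g in gids) {
      ssu <- .mutate_seq(ancestor, stats::rbinom(1, 300, 0.05), dna)
      aux <- aas[stats::runif(length(aas)) < aux_rate_per_aa]
      m <- knockout(template, aux)
      m$model_id <- g
      m$completeness <- completeness[[g]]
      prots <- character(0)
      k <- 0L
      for (i in 1:3) {               # background proteins
        k <- k + 1L
        prots[paste0(g, "_p", k)] <- .random_seq(sample(150:250, 1),
                                                 aa_alpha)
      }
      planted <- character(0)
      for (q in seq_len(nrow(scan))) {
        if (stats::runif(1) >= pep_gene_rate) next
        k <- k + 1L
        dom <- .mutate_seq(scan$sequence[q],
                           stats::rbinom(1, nchar(scan$sequence[q]),
                                         domain_mutation_rate), aa_alpha)
        prots[paste0(g, "_p", k)] <- paste0(.signal_prefix(), dom,
                                            .random_seq(20, aa_alpha))
        planted <- c(planted, scan$merops_id[q])
      }
      # one scrambled decoy domain (signal-positive, must yield no hit)
      k <- k + 1L
      src <- sample(nrow(scan), 1)
      decoy_id <- paste0(g, "_p", k)
      prots[decoy_id] <- paste0(
        .signal_prefix(),
        paste(sample(strsplit(scan$sequence[src], "")[[1]]), collapse = ""))
      genomes[[g]] <- list(ssu = ssu, proteins = prots,
                           completeness = completeness[[g]])
      models[[g]] <- m
      truth_aux[[g]] <- aux
      truth_pep[[g]] <- planted
      truth_decoy[[g]] <- decoy_id
    }
    all_prots <- unlist(lapply(genomes, `[[`, "proteins"))
    names(all_prots) <- unlist(lapply(genomes,
                                      function(g) names(g$proteins)))
    structure(list(
      catalog = reference_catalog(genomes),
      models = unname(models),
      scan_db = scan,
      signal_table = data.frame(protein_id = names(all_prots),
                                signal = predict_signal_peptide(all_prots) *
                                  1L,
                                stringsAsFactors = FALSE),
      medium = template_medium(),
      truth = list(auxotrophies = truth_aux,
                   secreted_peptidases = truth_pep,
                   decoy_proteins = truth_decoy,
                   completeness = completeness)),
      class = "synthetic_bundle")
  })
}

#' Region/group design of a synthetic study
#'
#' Default design mirroring the biology being emulated: small-intestine
#' regions are tilted toward high-auxotrophy genomes, the large intestine
#' toward peptidase-rich genomes.
#'
#' @param n_per_region Samples per gastrointestinal region.
#' @param aux_tilt Tilt strength toward high-auxotrophy genomes in the
#'   small intestine.
#' @param pep_tilt Tilt strength toward peptidase-rich genomes in the
#'   large intestine.
#' @return Design data.frame for [make_samples()].
#' @export
default_study_design <- function(n_per_region = 30, aux_tilt = 1.5,
                                 pep_tilt = 1.5) {
  data.frame(
    region = .region_levels(),
    group = NA_character_,
    n = n_per_region,
    aux_tilt = c(aux_tilt, aux_tilt, aux_tilt, 0),
    pep_tilt = c(0, 0, 0, pep_tilt),
    stringsAsFactors = FALSE)
}

#' Design of a synthetic SIBO contrast
#'
#' Duodenal samples only: the non-SIBO group keeps the small-intestine
#' auxotrophy tilt, the SIBO group has it attenuated and gains a tilt
#' toward peptidase-rich genomes (reduced auxotrophies, more extracellular
#' peptidase genes).
#'
#' @param n_per_group Samples per group.
#' @param aux_tilt,pep_tilt Tilt strengths (see [default_study_design()]).
#' @return Design data.frame for [make_samples()].
#' @export
sibo_study_design <- function(n_per_group = 30, aux_tilt = 1.5,
                              pep_tilt = 1.5) {
  data.frame(
    region = "duodenum",
    group = c("non-SIBO", "SIBO"),
    n = n_per_group,
    aux_tilt = c(aux_tilt, 0),
    pep_tilt = c(0, pep_tilt),
    stringsAsFactors = FALSE)
}

#' Draw synthetic samples from a catalog
#'
#' Per sample, genome weights are drawn from a Dirichlet distribution whose
#' concentration is tilted by the design effects:
#' `concentration_i = base * exp(aux_tilt * z_aux_i + pep_tilt * z_pep_i)`
#' with `z` the standardized planted auxotrophy (or secreted peptidase
#' gene) count of genome i. Reads are emitted as multinomial counts over
#' per-genome ASVs derived from the genome's 16S gene at identities
#' straddling the 97% mapping threshold: an exact ASV (100%), one at 97.0%
#' (mappable, boundary inclusive) and one at 95% (planted unmappable).
#'
#' @param bundle A `synthetic_bundle` from [make_catalog()].
#' @param design data.frame with columns `region`, `group`, `n` (>= 3),
#'   `aux_tilt`, `pep_tilt` (see [default_study_design()]).
#' @param read_depth Reads per sample (multinomial total, default 10000).
#' @param base_conc Baseline Dirichlet concentration per genome.
#' @param seed Integer seed.
#' @return List with `asvs` ([asv_table()]), `metadata` (sample_id,
#'   region, group), and `truth` (`samples` = per-sample tilts, `asvs` =
#'   per-ASV source genome, identity and mappability).
#' @export
make_samples <- function(bundle, design, read_depth = 10000,
                         base_conc = 1, seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("region", "group", "n", "aux_tilt", "pep_tilt") %in%
                  names(design)))
  if (any(design$n < 3))
    stop("need at least 3 samples per design row", call. = FALSE)
  .with_seed(seed, {
    dna <- c("A", "C", "G", "T")
    gids <- names(bundle$catalog$genomes)
    zscore <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else
      as.numeric(scale(x))
    z_aux <- zscore(lengths(bundle$truth$auxotrophies[gids]))
    z_pep <- zscore(lengths(bundle$truth$secreted_peptidases[gids]))

    # ASVs: 200-nt window of each genome's 16S at 100 / 97 / 95 % identity
    asv_len <- 200L
    win <- substr(vapply(bundle$catalog$genomes, `[[`, "", "ssu"),
                  51L, 50L + asv_len)
    asv_seqs <- character(0)
    asv_truth <- list()
    asv_genome <- character(0)
    split_frac <- c(hi = 0.65, mid = 0.25, lo = 0.10)
    for (i in seq_along(gids)) {
      ids <- paste0("ASV_", gids[i], c("_hi", "_mid", "_lo"))
      n_mut <- c(0L, 6L, 10L)        # 0/3/5% of 200 nt
      for (k in 1:3)
        asv_seqs[ids[k]] <- .mutate_seq(win[[i]], n_mut[k], dna)
      asv_genome[ids] <- gids[i]
      asv_truth[[i]] <- data.frame(
        asv_id = ids, genome_id = gids[i],
        identity = 100 * (asv_len - n_mut) / asv_len,
        mappable = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
    }
    asv_truth <- do.call(rbind, asv_truth)

    n_total <- sum(design$n)
    sample_ids <- sprintf("S%03d", seq_len(n_total))
    metadata <- data.frame(sample_id = sample_ids,
                           region = rep(design$region, design$n),
                           group = rep(design$group, design$n),
                           stringsAsFactors = FALSE)
    truth_samples <- data.frame(
      sample_id = sample_ids,
      aux_tilt = rep(design$aux_tilt, design$n),
      pep_tilt = rep(design$pep_tilt, design$n),
      stringsAsFactors = FALSE)

    counts <- matrix(0L, length(asv_seqs), n_total,
                     dimnames = list(names(asv_seqs), sample_ids))
    for (s in seq_len(n_total)) {
      conc <- base_conc * exp(truth_samples$aux_tilt[s] * z_aux +
                                truth_samples$pep_tilt[s] * z_pep)
      w <- stats::rgamma(length(gids), shape = conc, rate = 1)
      w <- w / sum(w)
      p_asv <- as.vector(w %o% split_frac)
      # ASV order: for genome i rows (hi, mid, lo) are consecutive
      p_ordered <- numeric(length(asv_seqs))
      for (k in 1:3)
        p_ordered[seq(k, by = 3, length.out = length(gids))] <-
          w * split_frac[k]
      counts[, s] <- stats::rmultinom(1, read_depth, p_ordered)
    }
    list(asvs = asv_table(asv_seqs, counts), metadata = metadata,
         truth = list(samples = truth_samples, asvs = asv_truth))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits every file format the pipeline consumes: 16S and protein FASTAs,
#' model JSONs, medium JSON, scan-database FASTA
#' (`merops_id|unit_start-unit_end` headers), signal table TSV, ASV FASTA
#' and counts TSV, sample metadata TSV, and the planted truth as JSON.
#'
#' @param bundle A `synthetic_bundle` from [make_catalog()].
#' @param samples Output of [make_samples()].
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_dataset <- function(bundle, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  gids <- names(bundle$catalog$genomes)
  ssu <- unlist(lapply(gids, function(g) {
    s <- bundle$catalog$genomes[[g]]$ssu
    stats::setNames(s, paste0(g, "|ssu", seq_along(s)))
  }))
  write_fasta(ssu, file.path(dir, "genomes_16S.fasta"))
  prots <- unlist(lapply(gids, function(g) {
    p <- bundle$catalog$genomes[[g]]$proteins
    stats::setNames(p, paste0(g, "|", names(p)))
  }))
  write_fasta(prots, file.path(dir, "proteins.fasta"))
  utils::write.table(
    data.frame(genome_id = gids,
               completeness = vapply(bundle$catalog$genomes, `[[`, 0,
                                     "completeness"),
               stringsAsFactors = FALSE),
    file.path(dir, "completeness.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (m in bundle$models)
    write_model(m, file.path(dir, "models", paste0(m$model_id, ".json")))
  jsonlite::write_json(as.list(bundle$medium),
                       file.path(dir, "medium.json"), auto_unbox = TRUE,
                       digits = NA)
  write_fasta(stats::setNames(
    bundle$scan_db$sequence,
    paste0(bundle$scan_db$merops_id, "|", bundle$scan_db$unit_start, "-",
           bundle$scan_db$unit_end)),
    file.path(dir, "scan_db.fasta"))
  utils::write.table(bundle$signal_table, file.path(dir, "signal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(samples$asvs$sequences, file.path(dir, "asvs.fasta"))
  utils::write.table(
    data.frame(asv_id = rownames(samples$asvs$counts),
               samples$asvs$counts, check.names = FALSE,
               stringsAsFactors = FALSE),
    file.path(dir, "asv_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(samples$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(auxotrophies = bundle$truth$auxotrophies,
         secreted_peptidases = bundle$truth$secreted_peptidases,
         decoy_proteins = bundle$truth$decoy_proteins,
         completeness = as.list(bundle$truth$completeness),
         samples = samples$truth$samples, asvs = samples$truth$asvs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `catalog`, `models`, `scan_db`, `signal_table`,
#'   `medium`, `asvs`, `metadata`.
#' @export
read_dataset <- function(dir) {
  ssu <- read_fasta(file.path(dir, "genomes_16S.fasta"))
  prots <- read_fasta(file.path(dir, "proteins.fasta"))
  comp <- utils::read.delim(file.path(dir, "completeness.tsv"),
                            stringsAsFactors = FALSE)
  ssu_gid <- sub("\\|.*$", "", names(ssu))
  prot_gid <- sub("\\|.*$", "", names(prots))
  prot_id <- sub("^[^|]*\\|", "", names(prots))
  genomes <- lapply(comp$genome_id, function(g) {
    list(ssu = unname(ssu[ssu_gid == g]),
         proteins = stats::setNames(unname(prots[prot_gid == g]),
                                    prot_id[prot_gid == g]),
         completeness = comp$completeness[comp$genome_id == g])
  })
  names(genomes) <- comp$genome_id
  models <- lapply(list.files(file.path(dir, "models"),
                              pattern = "\\.json$", full.names = TRUE),
                   read_model)
  med <- growth_medium(unlist(jsonlite::fromJSON(
    file.path(dir, "medium.json"))))
  sig <- utils::read.delim(file.path(dir, "signal.tsv"),
                           stringsAsFactors = FALSE)
  md <- utils::read.delim(file.path(dir, "metadata.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  list(catalog = reference_catalog(genomes), models = models,
       scan_db = read_scan_db(file.path(dir, "scan_db.fasta")),
       signal_table = sig, medium = med,
       asvs = read_asv_table(file.path(dir, "asvs.fasta"),
                             file.path(dir, "asv_counts.tsv")),
       metadata = md)
}
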
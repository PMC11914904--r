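# BLOSUM62 with the unknown residue X scored 0 against everything
.blosum62_x0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0
      m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

.check_protein <- function(seq, what) {
  if (!nzchar(seq)) stop(what, " sequence is empty", call. = FALSE)
  if (grepl(paste0("[^", paste(c(.protein_alphabet(), "X"), collapse = ""),
                   "]"), seq))
    stop(what, " sequence contains letters outside the 20-residue ",
         "alphabet (+X)", call. = FALSE)
  invisible(TRUE)
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Dynamic-programming local alignment under BLOSUM62 with affine gap
#' penalties: a gap of length L costs `gap_open + gap_extend * L`. The
#' unknown residue X scores 0 against everything. When no residue pair
#' scores positively the optimal local alignment is empty (score 0).
#'
#' @param query,target Protein sequences (uppercase, 20 letters + X).
#' @param gap_open,gap_extend Affine gap parameters (default 11 / 1).
#' @return List with `raw_score`, `query_span`, `target_span` (1-based
#'   inclusive; `NULL` spans for an empty alignment).
#' @export
local_align_protein <- function(query, target, gap_open = 11,
                                gap_extend = 1) {
  .check_protein(query, "query")
  .check_protein(target, "target")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    substitutionMatrix = .blosum62_x0(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  s <- Biostrings::score(pa)
  if (s <= 0)
    return(list(raw_score = 0, query_span = NULL, target_span = NULL))
  list(raw_score = s,
       query_span = c(Biostrings::start(Biostrings::pattern(pa)),
                      Biostrings::end(Biostrings::pattern(pa))),
       target_span = c(Biostrings::start(Biostrings::subject(pa)),
                       Biostrings::end(Biostrings::subject(pa))))
}

#' Karlin-Altschul bitscore and E-value
#'
#' `bitscore = (lambda * raw_score - ln K) / ln 2` and
#' `evalue = m * n * 2^(-bitscore)`, with lambda and K fixed at the gapped
#' BLOSUM62 defaults so scores are reproducible without a search heuristic.
#'
#' @param raw_score Nonnegative raw alignment score.
#' @param m Query length (residues).
#' @param n Database length (total residues searched).
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267, 0.041).
#' @return List with `bitscore` and `evalue`.
#' @export
karlin_altschul <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0", call. = FALSE)
  if (m <= 0 || n <= 0) stop("m and n must be positive", call. = FALSE)
  bitscore <- (lambda * raw_score - log(K)) / log(2)
  list(bitscore = bitscore, evalue = m * n * 2^(-bitscore))
}

.merops_id_ok <- function(id) {
  grepl("^[A-Z][0-9]{2}\\.[A-Z0-9]{3}$", id)
}

#' Read a MEROPS-style scan-sequence database
#'
#' FASTA with headers `merops_id|unit_start-unit_end`, where the span marks
#' the peptidase unit (catalytic domain) within the scan sequence.
#'
#' @param path FASTA path.
#' @return data.frame `merops_id`, `sequence`, `unit_start`, `unit_end`.
#' @export
read_scan_db <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  spans <- strsplit(vapply(parts, `[`, "", 2L), "-", fixed = TRUE)
  scan_db(data.frame(
    merops_id = vapply(parts, `[`, "", 1L),
    sequence = unname(seqs),
    unit_start = as.integer(vapply(spans, `[`, "", 1L)),
    unit_end = as.integer(vapply(spans, `[`, "", 2L)),
    stringsAsFactors = FALSE))
}

#' Validate a scan database
#'
#' @param db data.frame with `merops_id` (format letter + 2 digits + "." +
#'   3 alphanumerics, e.g. "S09.075" or "S09.A41"), `sequence`,
#'   `unit_start`, `unit_end` (1-based inclusive span within the
#'   sequence).
#' @return The validated data.frame (class `scan_db`).
#' @export
scan_db <- function(db) {
  if (!nrow(db)) stop("scan database is empty", call. = FALSE)
  bad <- !.merops_id_ok(db$merops_id)
  if (any(bad))
    stop("malformed merops_id(s): ",
         paste(db$merops_id[bad], collapse = ", "), call. = FALSE)
  if (any(db$unit_start < 1 | db$unit_end > nchar(db$sequence) |
          db$unit_start > db$unit_end))
    stop("unit span outside scan sequence", call. = FALSE)
  class(db) <- c("scan_db", "data.frame")
  db
}

#' Call peptidase genes by homology against a scan database
#'
#' Every scan sequence (the query) is locally aligned against every protein
#' of every genome. A hit is retained when all four filters hold:
#' `evalue < max_evalue`, `query_coverage > min_query_cov`,
#' `bitscore > min_bitscore`, and `unit_coverage >= min_unit_cov` (the unit
#' coverage threshold is inclusive, the other three strict). Query coverage
#' is the aligned fraction of the scan sequence; unit coverage the aligned
#' fraction of its annotated peptidase unit. The Karlin-Altschul database
#' length is the total residue count of the proteome being searched. A
#' protein may carry hits to several peptidase identifiers.
#'
#' @param catalog A [reference_catalog()].
#' @param db A [scan_db()].
#' @param max_evalue E-value cutoff (default 0.01, strict).
#' @param min_query_cov Percent scan-sequence coverage (default 85,
#'   strict).
#' @param min_bitscore Bitscore cutoff (default 100, strict).
#' @param min_unit_cov Percent peptidase-unit coverage (default 95,
#'   inclusive).
#' @return data.frame of retained hits: `protein_id`, `genome_id`,
#'   `merops_id`, `family`, `raw_score`, `bitscore`, `evalue`,
#'   `query_coverage`, `unit_coverage`.
#' @export
call_peptidases <- function(catalog, db, max_evalue = 0.01,
                            min_query_cov = 85, min_bitscore = 100,
                            min_unit_cov = 95) {
  db <- scan_db(as.data.frame(db))
  rows <- list()
  mat <- .blosum62_x0()
  for (gid in names(catalog$genomes)) {
    prots <- catalog$genomes[[gid]]$proteins
    if (!length(prots)) next
    n_db <- sum(nchar(prots))
    targets <- Biostrings::AAStringSet(prots)
    for (q in seq_len(nrow(db))) {
      qseq <- db$sequence[q]
      qlen <- nchar(qseq)
      ulen <- db$unit_end[q] - db$unit_start[q] + 1L
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(qseq, length(targets))), targets,
        substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
        type = "local")
      raw <- Biostrings::score(pa)
      qs <- Biostrings::start(Biostrings::pattern(pa))
      qe <- Biostrings::end(Biostrings::pattern(pa))
      ka <- karlin_altschul(pmax(raw, 0), qlen, n_db)
      qcov <- 100 * (qe - qs + 1L) / qlen
      overlap <- pmax(0L, pmin(qe, db$unit_end[q]) -
                        pmax(qs, db$unit_start[q]) + 1L)
      ucov <- 100 * overlap / ulen
      keep <- raw > 0 & ka$evalue < max_evalue & qcov > min_query_cov &
        ka$bitscore > min_bitscore & ucov >= min_unit_cov
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = names(prots)[keep], genome_id = gid,
        merops_id = db$merops_id[q],
        family = substr(db$merops_id[q], 1, 3),
        raw_score = raw[keep], bitscore = ka$bitscore[keep],
        evalue = ka$evalue[keep], query_coverage = qcov[keep],
        unit_coverage = ucov[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(protein_id = character(0), genome_id = character(0),
                      merops_id = character(0), family = character(0),
                      raw_score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), query_coverage = numeric(0),
                      unit_coverage = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Toy signal-peptide rule for synthetic proteomes
#'
#' Deterministic stand-in for a trained signal-peptide predictor, used only
#' with synthetic data: a protein is signal-positive iff residues 2-4
#' contain at least one K or R (n-region charge) and residues 5-25 contain
#' a run of at least 8 residues from \{L, A, V, I, F\} (h-region
#' hydrophobic core).
#'
#' @param seqs Character vector of protein sequences.
#' @return Logical vector.
#' @export
predict_signal_peptide <- function(seqs) {
  n_region <- grepl("[KR]", substr(seqs, 2, 4))
  h_region <- grepl("[LAVIF]{8}", substr(seqs, 5, 25))
  n_region & h_region
}

#' Aggregate extracellular peptidase genes per genome
#'
#' Keeps only hits on proteins carrying a signal peptide (putatively
#' secreted or surface-attached) and aggregates per genome: gene-copy
#' counts (each retained protein x peptidase hit counts once) and distinct
#' peptidase identifier counts, plus the per-genome identifier sets.
#' Proteins missing from the signal table are treated as signal-negative
#' (with a message).
#'
#' @param hits Hits from [call_peptidases()].
#' @param signal_table Either a named logical vector (protein_id ->
#'   signal) or a data.frame with columns `protein_id` and `signal`.
#' @param genomes Optional character vector of genome ids that must appear
#'   in the profile even with zero counts.
#' @return Object of class `peptidase_profile`: list with `copies`,
#'   `distinct` (named integer vectors), `merops_ids` (named list of
#'   character sets), and `hits` (the retained hit table).
#' @export
flag_extracellular <- function(hits, signal_table, genomes = NULL) {
  if (is.data.frame(signal_table))
    signal_table <- stats::setNames(as.logical(signal_table$signal),
                                    signal_table$protein_id)
  missing <- setdiff(unique(hits$protein_id), names(signal_table))
  if (length(missing))
    message(length(missing),
            " protein(s) missing from signal table; treated as negative")
  sig <- signal_table[hits$protein_id]
  sig[is.na(sig)] <- FALSE
  kept <- hits[sig, , drop = FALSE]
  gids <- sort(unique(c(genomes, hits$genome_id)))
  copies <- stats::setNames(integer(length(gids)), gids)
  distinct <- stats::setNames(integer(length(gids)), gids)
  sets <- stats::setNames(vector("list", length(gids)), gids)
  for (g in gids) {
    h <- kept[kept$genome_id == g, , drop = FALSE]
    copies[g] <- nrow(h)
    sets[[g]] <- sort(unique(h$merops_id))
    distinct[g] <- length(sets[[g]])
  }
  structure(list(copies = copies, distinct = distinct, merops_ids = sets,
                 hits = kept), class = "peptidase_profile")
}

#' @export
print.peptidase_profile <- function(x, ...) {
  cat("<peptidase_profile>", length(x$copies), "genomes;",
      sum(x$copies), "extracellular peptidase gene hits;",
      length(unique(unlist(x$merops_ids))), "distinct peptidase ids\n")
  invisible(x)
}
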
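#' Construct an ASV table
#'
#' Amplicon sequence variants (representative sequences) with per-sample
#' read counts. All ASVs must report counts for the same sample set.
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (names = ASV ids).
#' @param counts Nonnegative integer matrix, rows = ASV ids, columns =
#'   sample ids.
#' @return Object of class `asv_table`.
#' @export
asv_table <- function(sequences, counts) {
  counts <- as.matrix(counts)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("ASV sequences must be uniquely named", call. = FALSE)
  if (any(!nzchar(sequences)))
    stop("ASV sequences must be non-empty", call. = FALSE)
  if (!setequal(rownames(counts), names(sequences)))
    stop("count matrix rows must match ASV ids", call. = FALSE)
  counts <- counts[names(sequences), , drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(list(sequences = toupper(sequences), counts = counts),
            class = "asv_table")
}

#' Read an ASV table from FASTA + counts TSV
#'
#' @param fasta_path FASTA of representative ASV sequences.
#' @param counts_path TSV with column `asv_id` then one column per sample.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(fasta_path, counts_path) {
  seqs <- read_fasta(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cnt <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rn <- cnt[[1]]
  cnt <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(cnt) <- rn
  asv_table(seqs, cnt)
}

.iupac_ok <- function(seq) {
  !grepl("[^ACGTRYSWKMBDHVN]", seq)
}

# Semi-global alignment (ASV global, free end gaps on the reference) of
# every ASV against every 16S gene, both orientations, in one vectorized
# pass. With linear gap cost 2 (match +1 / mismatch -1), the match count
# follows algebraically from the score and the indel widths:
#   M = (score + La + I + 2 D) / 2,   columns = La + D
# (La = ASV length, I = inserted ASV positions, D = gap columns in the
# ASV), so identity = M / columns and coverage = (La - I) / La without
# materializing alignment strings.
.align_asv_all <- function(asv_seqs, subjects) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  n_asv <- length(asv_seqs)
  n_sub <- length(subjects)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(asv_seqs)))
  patterns <- Biostrings::DNAStringSet(
    rep(c(asv_seqs, rc), each = n_sub))
  subj_all <- rep(subjects, times = 2L * n_asv)
  pa <- Biostrings::pairwiseAlignment(
    patterns, subj_all, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, type = "global-local")
  ni <- Biostrings::nindel(pa)
  I <- Biostrings::insertion(ni)[, "WidthSum"]
  D <- Biostrings::deletion(ni)[, "WidthSum"]
  La <- rep(nchar(c(asv_seqs, rc)), each = n_sub)
  M <- (Biostrings::score(pa) + La + I + 2 * D) / 2
  identity <- 100 * M / (La + D)
  coverage <- 100 * (La - I) / La
  # fwd block then rc block; keep the better orientation per (asv, subject)
  block <- function(v, k) matrix(v[seq_len(n_sub * n_asv) +
                                     (k - 1L) * n_sub * n_asv],
                                 n_sub, n_asv)
  idf <- block(identity, 1L)
  idr <- block(identity, 2L)
  cvf <- block(coverage, 1L)
  cvr <- block(coverage, 2L)
  use_rev <- idr > idf
  list(identity = ifelse(use_rev, idr, idf),
       coverage = ifelse(use_rev, cvr, cvf))
}

#' Map ASVs to catalog genomes
#'
#' Each ASV is aligned (semi-globally, both orientations) against every 16S
#' gene in the catalog. Hits must meet both thresholds (inclusive), and per
#' ASV only hits at that ASV's maximum passing identity are retained --
#' possibly several genomes at the tied maximum. ASVs with no passing hit
#' are absent from the output.
#'
#' @param asvs An [asv_table()].
#' @param catalog A [reference_catalog()].
#' @param min_identity Minimum percent identity (default 97, inclusive).
#' @param min_query_cov Minimum percent ASV coverage (default 95,
#'   inclusive).
#' @return data.frame with columns `asv_id`, `genome_id`, `identity`,
#'   `query_coverage`.
#' @export
map_asvs <- function(asvs, catalog, min_identity = 97, min_query_cov = 95) {
  if (!length(catalog$genomes)) stop("catalog is empty", call. = FALSE)
  bad <- !vapply(asvs$sequences, .iupac_ok, TRUE)
  if (any(bad))
    stop("ASV sequence(s) with non-IUPAC characters: ",
         paste(names(asvs$sequences)[bad], collapse = ", "), call. = FALSE)
  gids <- names(catalog$genomes)
  ssu_genome <- rep(gids, vapply(catalog$genomes,
                                 function(g) length(g$ssu), 0L))
  subjects <- Biostrings::DNAStringSet(
    unlist(lapply(catalog$genomes, `[[`, "ssu"), use.names = FALSE))
  sc_all <- .align_asv_all(asvs$sequences, subjects)
  out <- vector("list", length(asvs$sequences))
  for (i in seq_along(asvs$sequences)) {
    # per genome: max identity over its 16S genes
    gid_id <- tapply(sc_all$identity[, i], ssu_genome, max)
    gid_cov <- tapply(sc_all$coverage[, i], ssu_genome, max)
    pass <- gid_id >= min_identity & gid_cov >= min_query_cov
    if (!any(pass)) next
    top <- max(gid_id[pass])
    keep <- pass & gid_id >= top - 1e-9
    out[[i]] <- data.frame(asv_id = names(asvs$sequences)[i],
                           genome_id = names(gid_id)[keep],
                           identity = unname(gid_id[keep]),
                           query_coverage = unname(gid_cov[keep]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(asv_id = character(0), genome_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-sample genome relative abundances from mapped ASVs
#'
#' Each mapped ASV's read counts are apportioned to its genomes -- split
#' equally among genomes tied at the maximum identity (`"equal_split"`,
#' default) or dropped when ambiguous (`"drop_ambiguous"`) -- summed per
#' genome, and normalized by the sample's total mapped reads. Samples with
#' zero mapped reads get an empty abundance map and are listed in
#' `unmapped_samples`.
#'
#' @param asvs An [asv_table()].
#' @param hits Mapping hits from [map_asvs()].
#' @param metadata Optional data.frame with columns `sample_id`, `region`,
#'   `group`.
#' @param ties Tie apportionment rule.
#' @return Object of class `sample_abundance`: list with `abund` (matrix
#'   samples x genomes, rows summing to 1), `metadata`, `unmapped_samples`.
#' @export
assign_abundance <- function(asvs, hits, metadata = NULL,
                             ties = c("equal_split", "drop_ambiguous")) {
  ties <- match.arg(ties)
  if (nrow(hits) && !all(hits$asv_id %in% names(asvs$sequences)))
    stop("hits refer to ASVs absent from the table", call. = FALSE)
  samples <- colnames(asvs$counts)
  split_hits <- split(hits$genome_id, hits$asv_id)
  if (ties == "drop_ambiguous")
    split_hits <- split_hits[lengths(split_hits) == 1L]
  genomes <- sort(unique(unlist(split_hits)))
  W <- matrix(0, length(samples), length(genomes),
              dimnames = list(samples, genomes))
  for (asv in names(split_hits)) {
    g <- split_hits[[asv]]
    W[, g] <- W[, g, drop = FALSE] +
      asvs$counts[asv, ] %o% rep(1 / length(g), length(g))
  }
  tot <- rowSums(W)
  unmapped <- samples[tot == 0]
  if (length(unmapped))
    message("sample(s) with zero mapped reads: ",
            paste(unmapped, collapse = ", "))
  A <- W[tot > 0, , drop = FALSE] / tot[tot > 0]
  md <- data.frame(sample_id = samples, region = NA_character_,
                   group = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    k <- match(samples, metadata$sample_id)
    if ("region" %in% names(metadata)) md$region <- metadata$region[k]
    if ("group" %in% names(metadata)) md$group <- metadata$group[k]
    bad_region <- !is.na(md$region) & !md$region %in% .region_levels()
    if (any(bad_region))
      stop("unknown region label(s): ",
           paste(unique(md$region[bad_region]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(abund = A, metadata = md, unmapped_samples = unmapped),
            class = "sample_abundance")
}

#' @export
print.sample_abundance <- function(x, ...) {
  cat("<sample_abundance>", nrow(x$abund), "samples x", ncol(x$abund),
      "genomes;", length(x$unmapped_samples), "unmapped sample(s)\n")
  invisible(x)
}

#' Write per-sample abundances in long format
#'
#' @param sa A `sample_abundance` object.
#' @param path Output TSV (columns sample_id, genome_id, rel_abundance).
#' @return Invisibly `path`.
#' @export
write_abundance <- function(sa, path) {
  long <- data.frame(
    sample_id = rep(rownames(sa$abund), ncol(sa$abund)),
    genome_id = rep(colnames(sa$abund), each = nrow(sa$abund)),
    rel_abundance = as.vector(sa$abund), stringsAsFactors = FALSE)
  long <- long[long$rel_abundance > 0, ]
  long <- long[order(long$sample_id, long$genome_id), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
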
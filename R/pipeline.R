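#' Pipeline configuration
#'
#' Bundles input location, thresholds and statistics options for
#' [run_pipeline()]. All thresholds are validated against their legal
#' ranges; the seed is mandatory because the statistics stage draws
#' permutations.
#'
#' @param input_dir Dataset directory (layout of [write_dataset()]).
#' @param output_dir Output directory for stage TSVs and the manifest.
#' @param seed Integer seed for all stochastic stages.
#' @param min_identity,min_query_cov ASV mapping thresholds (percent).
#' @param max_evalue,min_query_cov_pep,min_bitscore,min_unit_cov Peptidase
#'   calling thresholds.
#' @param min_completeness Completeness gate for the auxotrophy screen.
#' @param zero_tol No-growth threshold (flux units).
#' @param n_perm PERMANOVA permutations.
#' @param alpha Significance threshold for the differential screen.
#' @param counting_mode Peptidase counting mode (`"copies"` or
#'   `"distinct"`).
#' @param tie_rule ASV tie apportionment (`"equal_split"` or
#'   `"drop_ambiguous"`).
#' @param adjust P-value adjustment in the differential screen (`"BH"` or
#'   `"none"`).
#' @param paired_screen Treat the duodenum / large-intestine screen as
#'   paired (requires matched sample counts).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, seed,
                            min_identity = 97, min_query_cov = 95,
                            max_evalue = 0.01, min_query_cov_pep = 85,
                            min_bitscore = 100, min_unit_cov = 95,
                            min_completeness = 85, zero_tol = 1e-6,
                            n_perm = 999, alpha = 0.001,
                            counting_mode = c("copies", "distinct"),
                            tie_rule = c("equal_split", "drop_ambiguous"),
                            adjust = c("BH", "none"),
                            paired_screen = FALSE) {
  pct <- function(x) is.numeric(x) && x >= 0 && x <= 100
  stopifnot(pct(min_identity), pct(min_query_cov), pct(min_query_cov_pep),
            pct(min_unit_cov), pct(min_completeness),
            max_evalue > 0, min_bitscore >= 0, zero_tol > 0,
            n_perm >= 1, alpha > 0, alpha <= 1)
  if (missing(seed) || !is.numeric(seed))
    stop("seed is mandatory (statistics stage draws permutations)",
         call. = FALSE)
  structure(list(
    input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
    min_identity = min_identity, min_query_cov = min_query_cov,
    max_evalue = max_evalue, min_query_cov_pep = min_query_cov_pep,
    min_bitscore = min_bitscore, min_unit_cov = min_unit_cov,
    min_completeness = min_completeness, zero_tol = zero_tol,
    n_perm = as.integer(n_perm), alpha = alpha,
    counting_mode = match.arg(counting_mode),
    tie_rule = match.arg(tie_rule), adjust = match.arg(adjust),
    paired_screen = isTRUE(paired_screen)), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(df)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes map -> abundances -> auxotrophy screen -> peptidase calling ->
#' community metrics -> statistics on a dataset directory, writing
#' self-describing TSVs plus a JSON manifest (config hash, per-stage row
#' counts, timings, warnings). Given identical inputs and seed the
#' statistics outputs are byte-identical across runs.
#'
#' The statistics stage adapts to the available metadata: Kendall ordered
#' correlations per amino acid and the duodenum / large-intestine
#' differential peptidase screen need region labels; group contrasts
#' (per-amino-acid rank-sum tests, weighted-average tests, PERMANOVA,
#' median dissimilarity to the large intestine) need group labels.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   config_hash = .config_hash(config), stages = list())
  warns <- character(0)
  note <- function(stage, rows, secs)
    manifest$stages[[stage]] <<- list(rows = rows,
                                      seconds = round(secs, 2))
  tick <- function() proc.time()[["elapsed"]]

  ds <- read_dataset(config$input_dir)

  t0 <- tick()
  hits <- map_asvs(ds$asvs, ds$catalog, config$min_identity,
                   config$min_query_cov)
  note("map", .write_tsv(hits, file.path(out, "hits.tsv")), tick() - t0)
  unmapped_asvs <- setdiff(names(ds$asvs$sequences), hits$asv_id)
  if (length(unmapped_asvs))
    warns <- c(warns, paste0("unmapped ASVs: ",
                             paste(unmapped_asvs, collapse = ",")))

  t0 <- tick()
  sa <- withCallingHandlers(
    assign_abundance(ds$asvs, hits, ds$metadata, ties = config$tie_rule),
    message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  note("abundance", .write_tsv(
    data.frame(sample_id = rep(rownames(sa$abund), ncol(sa$abund)),
               genome_id = rep(colnames(sa$abund), each = nrow(sa$abund)),
               rel_abundance = as.vector(sa$abund)),
    file.path(out, "abundance.tsv")), tick() - t0)

  t0 <- tick()
  aux <- screen_catalog(ds$models, ds$medium,
                        min_completeness = config$min_completeness,
                        zero_tol = config$zero_tol)
  write_auxotrophy_profile(aux, file.path(out, "auxotrophy.tsv"),
                           file.path(out, "exclusions.tsv"))
  if (nrow(aux$excluded))
    warns <- c(warns, paste0("excluded genomes: ",
                             paste(aux$excluded$genome_id, collapse = ",")))
  note("screen_auxotrophy", nrow(aux$calls), tick() - t0)

  t0 <- tick()
  pep_hits <- call_peptidases(ds$catalog, ds$scan_db, config$max_evalue,
                              config$min_query_cov_pep,
                              config$min_bitscore, config$min_unit_cov)
  pep <- withCallingHandlers(
    flag_extracellular(pep_hits, ds$signal_table,
                       genomes = names(ds$catalog$genomes)),
    message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  .write_tsv(pep_hits, file.path(out, "peptidase_hits.tsv"))
  note("call_peptidases", .write_tsv(
    data.frame(genome_id = names(pep$copies),
               extracellular_gene_copies = unname(pep$copies),
               distinct_peptidases = unname(pep$distinct)),
    file.path(out, "peptidase_profile.tsv")), tick() - t0)

  t0 <- tick()
  metrics <- community_metrics(sa, aux, pep, mode = config$counting_mode)
  aux_mat <- auxotrophy_abundance_matrix(sa, aux)
  pep_mat <- peptidase_abundance_matrix(sa, pep)
  .write_tsv(data.frame(sample_id = rownames(aux_mat), aux_mat,
                        check.names = FALSE),
             file.path(out, "aux_abundance_matrix.tsv"))
  .write_tsv(data.frame(sample_id = rownames(pep_mat), pep_mat,
                        check.names = FALSE),
             file.path(out, "pep_abundance_matrix.tsv"))
  note("metrics", .write_tsv(metrics, file.path(out, "metrics.tsv")),
       tick() - t0)

  t0 <- tick()
  stats_out <- .pipeline_stats(metrics, aux_mat, pep_mat, config, out)
  warns <- c(warns, stats_out$warnings)
  note("stats", length(stats_out$written), tick() - t0)

  manifest$warnings <- warns
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(hits = hits, abundance = sa, auxotrophy = aux,
                 peptidase = pep, metrics = metrics,
                 aux_abundance = aux_mat, pep_abundance = pep_mat,
                 stats = stats_out, manifest = manifest))
}

# statistics stage: every contrast the metadata supports
.pipeline_stats <- function(metrics, aux_mat, pep_mat, config, out) {
  written <- character(0)
  warns <- character(0)
  res <- list()
  md <- metrics
  region_ok <- sum(!is.na(md$region)) >= 6 &&
    length(unique(stats::na.omit(md$region))) >= 2
  group_ok <- length(unique(stats::na.omit(md$group))) == 2

  if (region_ok) {
    rk <- region_rank(md$region)
    keep <- !is.na(rk)
    kend <- lapply(colnames(aux_mat), function(aa) {
      v <- aux_mat[md$sample_id[keep], aa]
      t <- kendall_ordered(v, rk[keep])
      data.frame(amino_acid = aa, tau = t$statistic, p = t$p_value)
    })
    kend <- do.call(rbind, kend)
    kend$p_adj <- bh_fdr(kend$p)
    .write_tsv(kend, file.path(out, "kendall_auxotrophy_region.tsv"))
    written <- c(written, "kendall_auxotrophy_region.tsv")
    res$kendall <- kend

    # duodenum vs large intestine differential peptidase screen
    duo <- md$sample_id[!is.na(md$region) & md$region == "duodenum"]
    li <- md$sample_id[!is.na(md$region) & md$region == "large_intestine"]
    if (length(duo) >= 3 && length(li) >= 3) {
      paired <- config$paired_screen && length(duo) == length(li)
      scr <- differential_peptidase_screen(
        pep_mat[li, , drop = FALSE], pep_mat[duo, , drop = FALSE],
        paired = paired, alpha = config$alpha, adjust = config$adjust)
      .write_tsv(scr, file.path(out, "screen_li_vs_duodenum.tsv"))
      written <- c(written, "screen_li_vs_duodenum.tsv")
      res$screen <- scr
    }

    # pairwise weighted-average contrasts across regions
    regs <- intersect(.region_levels(), unique(stats::na.omit(md$region)))
    pw <- list()
    for (i in seq_along(regs)) for (j in seq_len(i - 1L)) {
      a <- md[!is.na(md$region) & md$region == regs[j], ]
      b <- md[!is.na(md$region) & md$region == regs[i], ]
      for (metric in c("weighted_avg_auxotrophies",
                       "weighted_avg_peptidases")) {
        t <- wilcoxon_rank_sum(a[[metric]], b[[metric]])
        pw[[length(pw) + 1L]] <- data.frame(
          metric = metric, region_a = regs[j], region_b = regs[i],
          U = t$statistic, p = t$p_value, stringsAsFactors = FALSE)
      }
    }
    if (length(pw)) {
      pw <- do.call(rbind, pw)
      .write_tsv(pw, file.path(out, "weighted_avg_region_contrasts.tsv"))
      written <- c(written, "weighted_avg_region_contrasts.tsv")
      res$region_contrasts <- pw
    }
  }

  # ordination + PERMANOVA on peptidase profiles
  grouping <- if (region_ok) md$region else md$group
  ok <- !is.na(grouping) & rowSums(pep_mat[md$sample_id, , drop = FALSE],
                                   na.rm = TRUE) > 0
  if (sum(ok) >= 4 && length(unique(grouping[ok])) >= 2 &&
      all(table(grouping[ok]) >= 2)) {
    D <- withCallingHandlers(
      bray_curtis_matrix(pep_mat[md$sample_id[ok], , drop = FALSE]),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    pc <- pcoa(D)
    .write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                          pc$coordinates, check.names = FALSE),
               file.path(out, "pcoa_coordinates.tsv"))
    pm <- permanova(D, grouping[ok], n_perm = config$n_perm,
                    seed = config$seed)
    .write_tsv(data.frame(factor = if (region_ok) "region" else "group",
                          pseudo_F = pm$statistic, R2 = pm$R2,
                          p = pm$p_value, method = pm$method),
               file.path(out, "permanova.tsv"))
    written <- c(written, "pcoa_coordinates.tsv", "permanova.tsv")
    res$pcoa <- pc
    res$permanova <- pm
  }

  if (group_ok) {
    glev <- sort(unique(stats::na.omit(md$group)))
    a <- md[!is.na(md$group) & md$group == glev[1], ]
    b <- md[!is.na(md$group) & md$group == glev[2], ]
    if (nrow(a) >= 3 && nrow(b) >= 3) {
      ga <- lapply(colnames(aux_mat), function(aa) {
        t <- wilcoxon_rank_sum(aux_mat[a$sample_id, aa],
                               aux_mat[b$sample_id, aa])
        data.frame(amino_acid = aa, U = t$statistic, p = t$p_value)
      })
      ga <- do.call(rbind, ga)
      ga$p_adj <- bh_fdr(ga$p)
      wa <- wilcoxon_rank_sum(a$weighted_avg_auxotrophies,
                              b$weighted_avg_auxotrophies)
      wp <- wilcoxon_rank_sum(a$weighted_avg_peptidases,
                              b$weighted_avg_peptidases)
      gsum <- data.frame(
        metric = c("weighted_avg_auxotrophies", "weighted_avg_peptidases"),
        group_a = glev[1], group_b = glev[2],
        U = c(wa$statistic, wp$statistic), p = c(wa$p_value, wp$p_value),
        stringsAsFactors = FALSE)
      .write_tsv(ga, file.path(out, "group_auxotrophy_tests.tsv"))
      .write_tsv(gsum, file.path(out, "group_weighted_avg_tests.tsv"))
      written <- c(written, "group_auxotrophy_tests.tsv",
                   "group_weighted_avg_tests.tsv")
      res$group_aux <- ga
      res$group_summary <- gsum

      # median dissimilarity of grouped small-intestine samples to the
      # large-intestine reference profiles
      li <- md$sample_id[!is.na(md$region) &
                           md$region == "large_intestine"]
      si <- md$sample_id[!is.na(md$group)]
      si <- setdiff(si, li)
      if (length(li) >= 2 && length(si) >= 6) {
        refs <- lapply(li, function(s) pep_mat[s, ])
        diss <- vapply(si, function(s)
          median_dissimilarity_to_reference(pep_mat[s, ], refs), 0)
        dd <- data.frame(sample_id = si,
                         group = md$group[match(si, md$sample_id)],
                         median_bray_curtis_to_li = diss,
                         stringsAsFactors = FALSE)
        t <- wilcoxon_rank_sum(
          dd$median_bray_curtis_to_li[dd$group == glev[1]],
          dd$median_bray_curtis_to_li[dd$group == glev[2]])
        dd$group_test_p <- t$p_value
        .write_tsv(dd, file.path(out, "dissimilarity_to_li.tsv"))
        written <- c(written, "dissimilarity_to_li.tsv")
        res$dissimilarity <- dd
      }
    }
  }

  # auxotrophy x peptidase Spearman matrix (duodenum if labeled, else all)
  sel <- if (region_ok)
    md$sample_id[!is.na(md$region) & md$region == "duodenum"] else
      md$sample_id
  if (length(sel) >= 4) {
    sp <- spearman_matrix(aux_mat[sel, , drop = FALSE],
                          pep_mat[sel, , drop = FALSE])
    .write_tsv(sp, file.path(out, "spearman_aux_pep.tsv"))
    written <- c(written, "spearman_aux_pep.tsv")
    res$spearman <- sp
  }

  res$written <- written
  res$warnings <- warns
  res
}
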
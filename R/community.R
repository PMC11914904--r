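# Weights over profiled genomes: genomes present in the sample but absent
# from the profile (e.g. excluded by the completeness gate, or non-growing)
# are dropped and the remaining weights renormalized; the dropped fraction
# is reported via attribute "dropped_fraction".
.profiled_weights <- function(abund, profiled_ids) {
  keep <- names(abund) %in% profiled_ids
  dropped <- sum(abund[!keep])
  w <- abund[keep]
  tot <- sum(w)
  if (tot <= 0)
    return(structure(numeric(0), dropped_fraction = dropped))
  structure(w / tot, dropped_fraction = dropped)
}

#' Auxotrophy abundance of one amino acid in one sample
#'
#' Summed relative abundance of the genomes auxotrophic for the given amino
#' acid, with weights renormalized over profiled genomes.
#'
#' @param abund Named numeric vector of genome relative abundances for one
#'   sample.
#' @param profile An `auxotrophy_profile` from [screen_catalog()].
#' @param aa Amino-acid code (see [amino_acids()]).
#' @return Numeric in \[0, 1\] (NA when no genome of the sample is
#'   profiled), with attribute `dropped_fraction`.
#' @export
auxotrophy_abundance <- function(abund, profile, aa) {
  stopifnot(aa %in% amino_acids())
  profiled <- rownames(profile$calls)[!is.na(profile$calls[, aa])]
  w <- .profiled_weights(abund, profiled)
  if (!length(w))
    return(structure(NA_real_,
                     dropped_fraction = attr(w, "dropped_fraction")))
  aux <- names(w)[profile$calls[names(w), aa]]
  structure(sum(w[aux]), dropped_fraction = attr(w, "dropped_fraction"))
}

#' Abundance-weighted average number of auxotrophies in one sample
#'
#' Community mean of the per-genome auxotrophy count (0-20), weighted by
#' relative abundances renormalized over profiled genomes.
#'
#' @inheritParams auxotrophy_abundance
#' @return Numeric in \[0, 20\] (NA, with a warning, when no genome of the
#'   sample is profiled).
#' @export
weighted_avg_auxotrophies <- function(abund, profile) {
  profiled <- names(profile$n_auxotrophies)[!is.na(profile$n_auxotrophies)]
  w <- .profiled_weights(abund, profiled)
  if (!length(w)) {
    warning("no overlap between sample genomes and auxotrophy profile")
    return(structure(NA_real_,
                     dropped_fraction = attr(w, "dropped_fraction")))
  }
  structure(sum(w * profile$n_auxotrophies[names(w)]),
            dropped_fraction = attr(w, "dropped_fraction"))
}

#' Peptidase abundance of one peptidase species in one sample
#'
#' Summed relative abundance of the genomes that harbor at least one
#' extracellular homolog of the given peptidase identifier (presence
#' semantics: copy number does not matter here).
#'
#' @inheritParams auxotrophy_abundance
#' @param pep A `peptidase_profile` from [flag_extracellular()].
#' @param merops_id Peptidase identifier, e.g. `"S09.075"`.
#' @return Numeric in \[0, 1\], with attribute `dropped_fraction`.
#' @export
peptidase_abundance <- function(abund, pep, merops_id) {
  w <- .profiled_weights(abund, names(pep$copies))
  if (!length(w))
    return(structure(NA_real_,
                     dropped_fraction = attr(w, "dropped_fraction")))
  carriers <- names(w)[vapply(pep$merops_ids[names(w)],
                              function(s) merops_id %in% s, TRUE)]
  structure(sum(w[carriers]), dropped_fraction = attr(w, "dropped_fraction"))
}

#' Abundance-weighted average number of extracellular peptidase genes
#'
#' @inheritParams peptidase_abundance
#' @param mode Count gene copies (default) or distinct peptidase
#'   identifiers per genome.
#' @return Nonnegative numeric (NA, with a warning, on empty overlap).
#' @export
weighted_avg_peptidases <- function(abund, pep,
                                    mode = c("copies", "distinct")) {
  mode <- match.arg(mode)
  k <- if (mode == "copies") pep$copies else pep$distinct
  w <- .profiled_weights(abund, names(k))
  if (!length(w)) {
    warning("no overlap between sample genomes and peptidase profile")
    return(structure(NA_real_,
                     dropped_fraction = attr(w, "dropped_fraction")))
  }
  structure(sum(w * k[names(w)]),
            dropped_fraction = attr(w, "dropped_fraction"))
}

#' Bray-Curtis dissimilarity between two nonnegative profiles
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))` over the union of ids
#' (absent entries are 0). Symmetric, bounded in \[0, 1\], 0 iff the
#' profiles are equal; undefined (error) when both profiles are all zero.
#'
#' @param x,y Named numeric vectors (nonnegative).
#' @return Numeric in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("profiles must be nonnegative", call. = FALSE)
  ids <- union(names(x), names(y))
  if (is.null(ids)) {           # unnamed: positional
    n <- max(length(x), length(y))
    xx <- c(x, numeric(n - length(x)))
    yy <- c(y, numeric(n - length(y)))
  } else {
    xx <- stats::setNames(numeric(length(ids)), ids)
    yy <- xx
    xx[names(x)] <- x
    yy[names(y)] <- y
  }
  tot <- sum(xx) + sum(yy)
  if (tot == 0)
    stop("Bray-Curtis undefined: both profiles are all zero", call. = FALSE)
  1 - 2 * sum(pmin(xx, yy)) / tot
}

#' Median Bray-Curtis dissimilarity of a sample to a reference set
#'
#' Used to score how similar a small-intestine profile is to the set of
#' large-intestine profiles: the median (midpoint convention for even
#' counts) of the Bray-Curtis distances from the sample to every reference.
#'
#' @param x Named numeric profile of the focal sample.
#' @param references Non-empty list of reference profiles.
#' @return Numeric in \[0, 1\].
#' @export
median_dissimilarity_to_reference <- function(x, references) {
  if (!length(references))
    stop("reference set is empty", call. = FALSE)
  stats::median(vapply(references, function(r) bray_curtis(x, r), 0))
}

#' Range-scale a vector to \[0, 1\]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros.
#'
#' @param v Numeric vector (non-empty).
#' @return Numeric vector in \[0, 1\].
#' @export
range_scale <- function(v) {
  if (!length(v)) stop("cannot range-scale an empty vector", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Per-sample auxotrophy abundance matrix
#'
#' @param sa A `sample_abundance` from [assign_abundance()].
#' @param profile An `auxotrophy_profile`.
#' @return Matrix samples x 20 amino acids of auxotrophy abundances.
#' @export
auxotrophy_abundance_matrix <- function(sa, profile) {
  aas <- amino_acids()
  M <- matrix(NA_real_, nrow(sa$abund), length(aas),
              dimnames = list(rownames(sa$abund), aas))
  for (s in rownames(sa$abund))
    for (aa in aas)
      M[s, aa] <- as.numeric(auxotrophy_abundance(sa$abund[s, ], profile, aa))
  M
}

#' Per-sample peptidase abundance matrix
#'
#' Rows are samples, columns the union of extracellular peptidase
#' identifiers present in the profile; entries are peptidase abundances
#' (summed relative abundance of carrier genomes). These vectors are the
#' peptidase profiles used for Bray-Curtis distances, ordination and the
#' differential screen.
#'
#' @param sa A `sample_abundance`.
#' @param pep A `peptidase_profile`.
#' @return Matrix samples x peptidase ids.
#' @export
peptidase_abundance_matrix <- function(sa, pep) {
  ids <- sort(unique(unlist(pep$merops_ids)))
  M <- matrix(NA_real_, nrow(sa$abund), length(ids),
              dimnames = list(rownames(sa$abund), ids))
  for (s in rownames(sa$abund))
    for (id in ids)
      M[s, id] <- as.numeric(peptidase_abundance(sa$abund[s, ], pep, id))
  M
}

#' Community metrics table
#'
#' One row per sample: abundance-weighted average auxotrophies and
#' extracellular peptidase genes, together with the dropped (unprofiled)
#' abundance fractions and the sample metadata.
#'
#' @param sa A `sample_abundance`.
#' @param profile An `auxotrophy_profile`.
#' @param pep A `peptidase_profile`.
#' @param mode Peptidase counting mode, see [weighted_avg_peptidases()].
#' @return data.frame with one row per sample.
#' @export
community_metrics <- function(sa, profile, pep,
                              mode = c("copies", "distinct")) {
  mode <- match.arg(mode)
  rows <- lapply(rownames(sa$abund), function(s) {
    a <- sa$abund[s, ]
    wa <- suppressWarnings(weighted_avg_auxotrophies(a, profile))
    wp <- suppressWarnings(weighted_avg_peptidases(a, pep, mode))
    md <- sa$metadata[sa$metadata$sample_id == s, , drop = FALSE]
    data.frame(sample_id = s, region = md$region[1], group = md$group[1],
               weighted_avg_auxotrophies = as.numeric(wa),
               weighted_avg_peptidases = as.numeric(wp),
               dropped_fraction_aux = attr(wa, "dropped_fraction"),
               dropped_fraction_pep = attr(wp, "dropped_fraction"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Bray-Curtis distance matrix from profile rows
#'
#' @param M Matrix samples x features (nonnegative). Rows that are all zero
#'   are dropped with a warning (their dissimilarity is undefined).
#' @return A square symmetric labeled distance matrix.
#' @export
bray_curtis_matrix <- function(M) {
  zero <- rowSums(M) == 0
  if (any(zero)) {
    warning("dropping all-zero profile row(s): ",
            paste(rownames(M)[zero], collapse = ", "))
    M <- M[!zero, , drop = FALSE]
  }
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n))
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- bray_curtis(M[i, ], M[j, ])
    }
  D
}
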
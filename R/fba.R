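#' Flux-balance analysis
#'
#' Maximizes the flux through the biomass reaction subject to the
#' steady-state constraint `S v = 0` and the flux bounds of the model, with
#' the exchange-reaction lower bounds set from the growth medium: for each
#' exchange reaction, the lower bound is minus the medium's maximum uptake
#' rate if its metabolite is in the medium and 0 otherwise (secretion is
#' always allowed up to the model's upper bound).
#'
#' @param model A [metabolic_model()].
#' @param medium A [growth_medium()].
#' @param with_fluxes Also return the full flux vector.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `growth_rate` (biomass flux, defined only when optimal), and optionally
#'   `fluxes` (named by reaction id).
#' @export
solve_fba <- function(model, medium, with_fluxes = FALSE) {
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  met_ids <- model$metabolites$id
  n <- length(rxn_ids)
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n)
  ub <- numeric(n)
  for (k in seq_len(n)) {
    st <- model$reactions[[k]]$stoichiometry
    S[names(st), k] <- st
    lb[k] <- model$reactions[[k]]$lower_bound
    ub[k] <- model$reactions[[k]]$upper_bound
  }
  # medium overrides exchange lower bounds
  for (met in names(model$exchange_map)) {
    k <- match(model$exchange_map[[met]], rxn_ids)
    lb[k] <- if (met %in% names(medium)) -medium[[met]] else 0
  }
  obj <- as.numeric(rxn_ids == model$biomass_reaction_id)
  sol <- solve_lp(obj, S, lb = lb, ub = ub, maximize = TRUE)
  out <- list(status = sol$status,
              growth_rate = if (sol$status == "optimal") sol$objective else
                NA_real_)
  if (with_fluxes && sol$status == "optimal")
    out$fluxes <- stats::setNames(sol$solution, rxn_ids)
  out
}

#' Leave-one-out amino-acid auxotrophy prediction for one model
#'
#' Growth is first computed on the full medium, then re-computed 20 times
#' with the focal amino acid's medium entry removed. A genome is called
#' auxotrophic for an amino acid when it grows on the full medium
#' (`growth_full >= zero_tol`) but not without that amino acid
#' (`growth_without < zero_tol`). Amino acids without an exchange mapping in
#' the model cannot be withdrawn and are scored prototrophic-by-absence
#' (noted in the result). A model that does not grow on the full medium is
#' flagged non-growing and all calls are `NA`.
#'
#' @param model A [metabolic_model()].
#' @param medium Full [growth_medium()]; must contain every mapped
#'   amino-acid metabolite.
#' @param aa_exchange_map Named character vector amino acid ->
#'   extracellular metabolite id (default [default_aa_exchange_map()]).
#' @param zero_tol Growth threshold below which growth counts as zero
#'   (absolute, flux units).
#' @return List with `calls` (named logical over [amino_acids()]),
#'   `n_auxotrophies`, `growth_full`, `non_growing`, and `notes`.
#' @export
predict_auxotrophies <- function(model, medium,
                                 aa_exchange_map = default_aa_exchange_map(),
                                 zero_tol = 1e-6) {
  aas <- amino_acids()
  model_mets <- model$metabolites$id
  mapped <- aa_exchange_map[names(aa_exchange_map) %in% aas]
  present <- mapped[mapped %in% model_mets]
  absent_med <- setdiff(unname(present), names(medium))
  if (length(absent_med))
    stop("full medium is missing mapped amino-acid metabolite(s): ",
         paste(absent_med, collapse = ", "), call. = FALSE)

  full <- solve_fba(model, medium)
  calls <- stats::setNames(rep(NA, length(aas)), aas)
  notes <- character(0)
  if (full$status != "optimal" || full$growth_rate < zero_tol) {
    return(list(calls = calls, n_auxotrophies = NA_integer_,
                growth_full = if (full$status == "optimal")
                  full$growth_rate else NA_real_,
                non_growing = TRUE,
                notes = "no growth on full medium; calls undefined"))
  }
  for (aa in aas) {
    met <- if (aa %in% names(mapped)) mapped[[aa]] else NA_character_
    if (is.na(met) || !met %in% model_mets) {
      calls[aa] <- FALSE
      notes <- c(notes, paste0(aa, ": no exchange mapping; ",
                               "prototroph-by-absence"))
      next
    }
    med_wo <- medium[names(medium) != met]
    wo <- solve_fba(model, growth_medium(med_wo))
    gw <- if (wo$status == "optimal") wo$growth_rate else 0
    calls[aa] <- gw < zero_tol
  }
  list(calls = calls, n_auxotrophies = sum(calls),
       growth_full = full$growth_rate, non_growing = FALSE, notes = notes)
}

#' Auxotrophy screen over a model catalog
#'
#' Applies [predict_auxotrophies()] to every model whose genome completeness
#' passes the gate (inclusive: completeness >= `min_completeness` is kept).
#' Excluded models, and models that do not grow on the full medium, are
#' listed in the exclusion report with a reason.
#'
#' @param models List of [metabolic_model()] objects with unique ids.
#' @param medium Full [growth_medium()].
#' @param aa_exchange_map Amino acid -> extracellular metabolite id.
#' @param min_completeness Completeness gate in percent (default 85,
#'   inclusive).
#' @param zero_tol Growth threshold, see [predict_auxotrophies()].
#' @return An `auxotrophy_profile`: list with `calls` (genome x 20 logical
#'   matrix), `n_auxotrophies`, `growth_full` (named numeric vectors), and
#'   `excluded` (data.frame genome_id/completeness/reason).
#' @export
screen_catalog <- function(models, medium,
                           aa_exchange_map = default_aa_exchange_map(),
                           min_completeness = 85, zero_tol = 1e-6) {
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids))
    stop("duplicate model_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!length(models))
    warning("empty model list: returning empty auxotrophy profile")
  aas <- amino_acids()
  calls <- matrix(NA, 0, length(aas), dimnames = list(NULL, aas))
  n_aux <- numeric(0)
  growth <- numeric(0)
  excl <- data.frame(genome_id = character(0), completeness = numeric(0),
                     reason = character(0), stringsAsFactors = FALSE)
  for (m in models) {
    if (m$completeness < min_completeness) {
      excl <- rbind(excl, data.frame(
        genome_id = m$model_id, completeness = m$completeness,
        reason = sprintf("completeness %.1f below gate %.1f",
                         m$completeness, min_completeness),
        stringsAsFactors = FALSE))
      next
    }
    p <- predict_auxotrophies(m, medium, aa_exchange_map, zero_tol)
    if (p$non_growing)
      excl <- rbind(excl, data.frame(
        genome_id = m$model_id, completeness = m$completeness,
        reason = "no growth on full medium", stringsAsFactors = FALSE))
    calls <- rbind(calls, p$calls)
    rownames(calls)[nrow(calls)] <- m$model_id
    n_aux[m$model_id] <- p$n_auxotrophies
    growth[m$model_id] <- p$growth_full
  }
  structure(list(calls = calls, n_auxotrophies = n_aux,
                 growth_full = growth, excluded = excl),
            class = "auxotrophy_profile")
}

#' @export
print.auxotrophy_profile <- function(x, ...) {
  cat("<auxotrophy_profile>", nrow(x$calls), "genomes profiled,",
      nrow(x$excluded), "excluded; median auxotrophies:",
      stats::median(x$n_auxotrophies, na.rm = TRUE), "\n")
  invisible(x)
}

#' Write an auxotrophy profile to TSV
#'
#' One row per genome: 0/1 columns per amino acid, `n_auxotrophies`,
#' `growth_full`. The exclusion report goes to a second file when given.
#'
#' @param profile An `auxotrophy_profile` from [screen_catalog()].
#' @param path Output TSV path.
#' @param exclusions_path Optional path for the exclusion report TSV.
#' @return Invisibly `path`.
#' @export
write_auxotrophy_profile <- function(profile, path, exclusions_path = NULL) {
  df <- data.frame(genome_id = rownames(profile$calls),
                   profile$calls * 1L,
                   n_auxotrophies = unname(profile$n_auxotrophies),
                   growth_full = unname(profile$growth_full),
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(exclusions_path))
    utils::write.table(profile$excluded, exclusions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
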
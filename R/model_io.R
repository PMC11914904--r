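#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` is a stoichiometric network with flux bounds, a
#' biomass objective reaction, and a map of exchange reactions through which
#' extracellular metabolites enter or leave the system (negative flux =
#' uptake, positive = secretion). Models are the unit of auxotrophy
#' prediction: one model per reference genome.
#'
#' @param model_id Single string identifying the model (usually genome id).
#' @param metabolites data.frame with columns `id` and `compartment`
#'   (`"cytosol"` or `"extracellular"`).
#' @param reactions List of reactions, each a list with `id`, `stoichiometry`
#'   (named numeric: metabolite id -> signed coefficient), `lower_bound`,
#'   `upper_bound`.
#' @param biomass_reaction_id Reaction id of the biomass pseudo-reaction.
#' @param exchange_map Named character vector: extracellular metabolite id ->
#'   exchange reaction id.
#' @param completeness Genome completeness percentage in \[0, 100\].
#' @return An object of class `metabolic_model`.
#' @seealso [read_model()], [write_model()], [solve_fba()]
#' @export
metabolic_model <- function(model_id, metabolites, reactions,
                            biomass_reaction_id, exchange_map,
                            completeness = 100) {
  m <- structure(list(
    model_id = as.character(model_id),
    metabolites = data.frame(id = as.character(metabolites$id),
                             compartment = as.character(metabolites$compartment),
                             stringsAsFactors = FALSE),
    reactions = lapply(reactions, function(r) {
      list(id = as.character(r$id),
           stoichiometry = unlist(r$stoichiometry),
           lower_bound = as.numeric(r$lower_bound),
           upper_bound = as.numeric(r$upper_bound))
    }),
    biomass_reaction_id = as.character(biomass_reaction_id),
    exchange_map = exchange_map,
    completeness = as.numeric(completeness)
  ), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks all structural invariants: declared metabolites, ordered bounds,
#' existing biomass reaction, one-metabolite extracellular exchange reactions
#' with coefficient -1, and completeness in \[0, 100\]. All violations are
#' collected and reported together.
#'
#' @param m A `metabolic_model`.
#' @return Invisibly `TRUE`; stops with a validation error listing all
#'   failures otherwise.
#' @export
validate_model <- function(m) {
  errs <- character(0)
  met_ids <- m$metabolites$id
  if (anyDuplicated(met_ids))
    errs <- c(errs, "duplicate metabolite ids")
  bad_comp <- setdiff(unique(m$metabolites$compartment),
                      c("cytosol", "extracellular"))
  if (length(bad_comp))
    errs <- c(errs, paste0("unknown compartment(s): ",
                           paste(bad_comp, collapse = ", ")))
  rxn_ids <- vapply(m$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    errs <- c(errs, "duplicate reaction ids")
  ext_ids <- met_ids[m$metabolites$compartment == "extracellular"]
  for (r in m$reactions) {
    undeclared <- setdiff(names(r$stoichiometry), met_ids)
    if (length(undeclared))
      errs <- c(errs, paste0("reaction ", r$id, ": undeclared metabolite(s) ",
                             paste(undeclared, collapse = ", ")))
    if (!length(r$stoichiometry))
      errs <- c(errs, paste0("reaction ", r$id, ": empty stoichiometry"))
    if (is.na(r$lower_bound) || is.na(r$upper_bound) ||
        r$lower_bound > r$upper_bound)
      errs <- c(errs, paste0("reaction ", r$id, ": lower_bound > upper_bound"))
  }
  if (!m$biomass_reaction_id %in% rxn_ids)
    errs <- c(errs, paste0("biomass_reaction_id '", m$biomass_reaction_id,
                           "' not among reactions"))
  if (length(m$exchange_map)) {
    if (is.null(names(m$exchange_map)) || anyDuplicated(names(m$exchange_map)))
      errs <- c(errs, "exchange_map must be uniquely named by metabolite id")
    for (met in names(m$exchange_map)) {
      rid <- m$exchange_map[[met]]
      k <- match(rid, rxn_ids)
      if (is.na(k)) {
        errs <- c(errs, paste0("exchange reaction '", rid, "' not found"))
        next
      }
      st <- m$reactions[[k]]$stoichiometry
      if (length(st) != 1L || names(st) != met || st[[1]] != -1)
        errs <- c(errs, paste0("exchange reaction ", rid,
                               ": must have exactly {", met, ": -1}"))
      if (!met %in% ext_ids)
        errs <- c(errs, paste0("exchange metabolite ", met,
                               " is not extracellular"))
    }
  }
  if (is.na(m$completeness) || m$completeness < 0 || m$completeness > 100)
    errs <- c(errs, "completeness must be in [0, 100]")
  if (length(errs))
    stop("invalid metabolic model '", m$model_id, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$model_id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", length(x$reactions),
      " exchanges:", length(x$exchange_map),
      " completeness:", x$completeness, "%\n")
  invisible(x)
}

#' Read a metabolic model from file
#'
#' The canonical interchange format is a documented JSON dialect with keys
#' `model_id`, `metabolites` (array of `{id, compartment}`), `reactions`
#' (array of `{id, stoichiometry, lower_bound, upper_bound}`), `biomass`,
#' `exchanges` (object metabolite -> reaction), `completeness`. SBML Level
#' 2/3 import maps species, reactions and (fbc) flux bounds onto the same
#' structure; compartments other than an extracellular one are mapped to
#' cytosol with a warning, and boundary species are treated as extracellular.
#'
#' @param path Path to the model file.
#' @param format `"json"` (default) or `"sbml"`.
#' @param completeness Completeness to assign when the format does not carry
#'   one (SBML); ignored for JSON.
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("json", "sbml"), completeness = 100) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "json") .read_model_json(path) else
    .read_model_sbml(path, completeness)
}

.read_model_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("malformed model JSON in ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  need <- c("model_id", "metabolites", "reactions", "biomass", "exchanges",
            "completeness")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("malformed model JSON: missing element(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(mt) {
    if (is.null(mt$id) || is.null(mt$compartment))
      stop("malformed model JSON: metabolite without id/compartment",
           call. = FALSE)
    data.frame(id = mt$id, compartment = mt$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(x$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop("malformed model JSON: reaction without id/stoichiometry",
           call. = FALSE)
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound)
  })
  metabolic_model(x$model_id, mets, rxns, x$biomass,
                  unlist(x$exchanges), x$completeness)
}

#' Write a metabolic model to the canonical JSON dialect
#'
#' `read_model(write_model(m))` reproduces `m` field by field, and writing a
#' freshly read file reproduces it byte for byte.
#'
#' @param m A `metabolic_model`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_model <- function(m, path) {
  validate_model(m)
  x <- list(
    model_id = m$model_id,
    metabolites = lapply(seq_len(nrow(m$metabolites)), function(i)
      list(id = m$metabolites$id[i],
           compartment = m$metabolites$compartment[i])),
    reactions = lapply(m$reactions, function(r)
      list(id = r$id, stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound)),
    biomass = m$biomass_reaction_id,
    exchanges = as.list(m$exchange_map),
    completeness = m$completeness
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML import (level 2/3 core + fbc bounds/objective) ------------------

.read_model_sbml <- function(path, completeness = 100) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed SBML in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  # namespace-agnostic XPath via local-name(): SBML core and fbc elements
  find_all <- function(node, name)
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    stop("malformed SBML: no <model> element", call. = FALSE)

  comps <- find_all(model, "compartment")
  comp_ids <- xml2::xml_attr(comps, "id")
  comp_names <- xml2::xml_attr(comps, "name")
  is_ext <- grepl("extracell|external|^e$|_e$", paste(comp_ids, comp_names),
                  ignore.case = TRUE)
  comp_map <- stats::setNames(ifelse(is_ext, "extracellular", "cytosol"),
                              comp_ids)
  if (sum(!is_ext) > 1L)
    warning("SBML model has ", sum(!is_ext),
            " non-extracellular compartments; all mapped to cytosol")

  params <- find_all(model, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  species <- find_all(model, "species")
  sp_id <- xml2::xml_attr(species, "id")
  sp_comp <- xml2::xml_attr(species, "compartment")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in%
    c("true", "1")
  sp_compartment <- ifelse(sp_boundary, "extracellular",
                           unname(comp_map[sp_comp]))
  sp_compartment[is.na(sp_compartment)] <- "cytosol"
  mets <- data.frame(id = sp_id, compartment = sp_compartment,
                     stringsAsFactors = FALSE)

  rnodes <- find_all(model, "reaction")
  if (!length(rnodes)) stop("malformed SBML: no reactions", call. = FALSE)
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        rn, paste0("./*[local-name()='", side,
                   "']/*[local-name()='speciesReference']"))
      if (!length(refs)) next
      sgn <- if (side == "listOfReactants") -1 else 1
      sid <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      for (i in seq_along(sid))
        st[sid[i]] <- (if (sid[i] %in% names(st)) st[[sid[i]]] else 0) +
          sgn * coef[i]
    }
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    reversible <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else
      if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else
      1000
    list(id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub)
  })

  # biomass: fbc active objective if present, else id/name matching "biomass"
  obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass <- if (!inherits(obj, "xml_missing"))
    xml2::xml_attr(obj, "reaction") else {
      rid <- vapply(rxns, `[[`, "", "id")
      hit <- grep("biomass", rid, ignore.case = TRUE, value = TRUE)
      if (!length(hit))
        stop("SBML import: no fbc objective and no reaction id matching ",
             "'biomass'", call. = FALSE)
      hit[1]
    }

  # exchange reactions: single extracellular metabolite with coefficient -1
  ext <- mets$id[mets$compartment == "extracellular"]
  exch <- character(0)
  for (r in rxns) {
    st <- r$stoichiometry
    if (length(st) == 1L && names(st) %in% ext && st[[1]] == -1)
      exch[names(st)] <- r$id
  }
  metabolic_model(xml2::xml_attr(model, "id"), mets, rxns, biomass, exch,
                  completeness)
}

# --- FASTA ----------------------------------------------------------------

#' Read a FASTA file
#'
#' Order-preserving FASTA reader (via Biostrings). Sequences are uppercased;
#' multi-line records are concatenated. An empty file yields an empty vector;
#' a record with an empty sequence is an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (names = full headers, in file order).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  ss <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA record with empty sequence in ", path, ": ",
         paste(names(ss)[Biostrings::width(ss) == 0L], collapse = ", "),
         call. = FALSE)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# --- growth medium --------------------------------------------------------

#' Define an in-silico growth medium
#'
#' A growth medium is the set of extracellular metabolites available for
#' uptake, with nonnegative maximum uptake rates (abstract, consistent flux
#' units). During FBA the lower bound of each exchange reaction is set to
#' minus the uptake rate if its metabolite is in the medium and to 0
#' otherwise; secretion is always allowed up to the model's upper bound.
#'
#' @param entries Named numeric vector: extracellular metabolite id ->
#'   maximum uptake rate (>= 0).
#' @return Object of class `growth_medium` (a named numeric vector).
#' @export
growth_medium <- function(entries) {
  entries <- unlist(entries)
  if (length(entries) && (is.null(names(entries)) || any(names(entries) == "")))
    stop("growth medium entries must be named by metabolite id", call. = FALSE)
  if (anyDuplicated(names(entries)))
    stop("duplicate metabolite ids in growth medium", call. = FALSE)
  if (any(entries < 0))
    stop("growth medium uptake rates must be nonnegative", call. = FALSE)
  structure(as.numeric(entries), names = names(entries),
            class = "growth_medium")
}

# --- reference genome catalog ---------------------------------------------

#' Construct a reference genome catalog
#'
#' A catalog holds, per genome, its 16S rRNA gene sequence(s), its protein
#' sequences, and an assembly completeness percentage. It is the mapping
#' target for ASVs and the proteome source for peptidase calling.
#'
#' @param genomes Named list; each element a list with `ssu` (character
#'   vector of 16S sequences), `proteins` (named character vector of protein
#'   sequences), `completeness` (percent).
#' @return Object of class `reference_catalog`.
#' @export
reference_catalog <- function(genomes) {
  if (!length(genomes) || is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("catalog genomes must be a non-empty uniquely named list",
         call. = FALSE)
  for (g in names(genomes)) {
    gen <- genomes[[g]]
    if (!length(gen$ssu) || any(!nzchar(gen$ssu)))
      stop("genome ", g, ": 16S sequences missing or empty", call. = FALSE)
    if (length(gen$proteins) && any(!nzchar(gen$proteins)))
      stop("genome ", g, ": empty protein sequence", call. = FALSE)
    if (is.null(gen$completeness) || gen$completeness < 0 ||
        gen$completeness > 100)
      stop("genome ", g, ": completeness must be in [0, 100]", call. = FALSE)
  }
  structure(list(genomes = genomes), class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  np <- sum(vapply(x$genomes, function(g) length(g$proteins), 0L))
  cat("<reference_catalog>", length(x$genomes), "genomes,", np, "proteins\n")
  invisible(x)
}
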
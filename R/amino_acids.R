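#' The twenty proteinogenic amino acids
#'
#' Canonical three-letter codes for the 20 proteinogenic amino acids, in
#' alphabetical order. All auxotrophy calls and community metrics are keyed
#' by these codes, so a genome can carry between 0 and 20 auxotrophies.
#'
#' @return Character vector of length 20.
#' @examples
#' amino_acids()
#' @export
amino_acids <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

#' Default mapping from amino acids to extracellular metabolite identifiers
#'
#' Models built by [make_template_model()] (and any model following the same
#' naming scheme) represent the extracellular pool of amino acid `X` as
#' metabolite `aa_X_e`. This helper returns that mapping for use with
#' [predict_auxotrophies()] and [screen_catalog()].
#'
#' @param aa_codes Character vector of amino-acid codes (default all 20).
#' @return Named character vector: amino acid code -> extracellular
#'   metabolite id.
#' @export
default_aa_exchange_map <- function(aa_codes = amino_acids()) {
  stats::setNames(paste0("aa_", aa_codes, "_e"), aa_codes)
}

# single-letter alphabet used for protein sequences (X = unknown residue)
.protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.region_levels <- function() {
  c("duodenum", "jejunum", "farthest_distance", "large_intestine")
}

#' Ordered rank of gastrointestinal regions
#'
#' Regions are treated as an ordered factor along the intestinal tract:
#' duodenum (1), jejunum (2), farthest distance reached in the small
#' intestine (3), large intestine (4).
#'
#' @param region Character vector of region labels.
#' @return Integer vector of ranks 1-4 (NA for missing labels).
#' @export
region_rank <- function(region) {
  match(region, .region_levels())
}
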
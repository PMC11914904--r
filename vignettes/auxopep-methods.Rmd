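---
title: "Methods: auxotrophy and peptidase profiling of gut communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auxotrophy and peptidase profiling of gut communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxopep)
```

`auxopep` asks, for a set of gut microbiome samples: how abundant are
bacteria that cannot synthesize particular amino acids, how abundant are
genes for peptidases that act outside the cell, and how do both change
along the intestinal tract and in dysbiosis? This vignette documents the
models and procedures behind each stage, the tunable parameters, the
synthetic data used to validate the pipeline, and the numerical and design
choices a maintainer should know about.

## From reads to genome abundances

The unit of observation is an amplicon sequence variant (ASV): an exact
denoised 16S rRNA gene fragment with per-sample read counts. ASV inference
itself is out of scope — the ASV table is an input. Each ASV is assigned to
reference genomes by pairwise alignment against every 16S gene in the
catalog:

* **Alignment model.** Semi-global: the ASV must align end-to-end, the
  reference provides free end gaps. Scoring is match +1 / mismatch −1 /
  gap −2 (linear). Identity is matches divided by ASV alignment columns;
  query coverage is aligned ASV positions over ASV length. Both
  orientations are tried and the better one used, since read orientation is
  not guaranteed. For a genome with several 16S genes, the genome's
  identity is the maximum over its genes.
* **Thresholds.** Hits require identity ≥ 97 % and query coverage ≥ 95 %,
  both inclusive; among passing hits, only those at the ASV's maximum
  identity are kept, possibly several genomes tied at that maximum.
* **Tie apportionment.** Read counts of a tied ASV are split equally across
  its genomes (default) or the ASV is dropped (`drop_ambiguous`). Equal
  splitting keeps total evidence; it was an open choice because keeping all
  maximum-identity hits says nothing about how to apportion counts.
* **Normalization.** Per sample, genome counts are divided by the sample's
  total mapped reads, so abundances sum to 1 whenever at least one read
  maps; samples with no mapped reads are flagged and excluded from
  downstream metrics.

The implementation delegates the dynamic programming to
`Biostrings::pairwiseAlignment` and recovers match counts algebraically
from the score and the insertion/deletion widths (for linear gap cost *g*,
M = (score + L + I + 2D)/2 with L the ASV length), avoiding expensive
alignment-string materialization; tests verify the identity values exactly
on planted-mismatch constructions.

## Auxotrophy prediction by flux-balance analysis

Each reference genome comes with a genome-scale metabolic model: a
stoichiometric matrix *S*, flux bounds, a biomass pseudo-reaction, and
exchange reactions (one extracellular metabolite each, coefficient −1, so
negative flux is uptake). Models and the growth medium are inputs; model
reconstruction and medium inference are out of scope. The growth medium
lists maximum uptake rates; during FBA each exchange lower bound becomes
−uptake if its metabolite is in the medium and 0 otherwise, while secretion
stays limited only by the model's upper bound. Flux units are treated as
abstract, consistent units.

Growth is the optimum of the linear program

> maximize *v*<sub>biomass</sub> subject to *S v* = 0, lb ≤ *v* ≤ ub.

No LP solver ships with the pre-installed R stack, so the package carries a
dense two-phase primal simplex with Bland's rule — deterministic, no
randomized restarts, pivot tolerance 10⁻⁹. It detects infeasible and
unbounded systems, and agrees with an exhaustive basic-feasible-solution
oracle to well below 10⁻⁷ on hundreds of random networks (only the
objective value is used downstream, so alternate optima are irrelevant).

**Leave-one-out screening.** For each of the 20 amino acids, growth is
recomputed with that amino acid's entry removed from the medium. A genome
is auxotrophic for amino acid *a* iff growth without *a* falls below
`zero_tol` while growth on the full medium is at least `zero_tol`. Choices
worth noting:

* `zero_tol = 1e-6` flux units (configurable). "No growth" needs a
  threshold; an absolute tolerance is the simplest reproducible reading and
  is far below any genuine growth optimum in the models used here.
* Only the free amino acid's exchange entry is removed; peptide carriers,
  if a model had them, are untouched (flag `remove_peptide_carriers` is
  deliberately not implemented as removal is the non-default reading).
* An amino acid with no exchange mapping in a model cannot be withdrawn;
  it is scored prototrophic-by-absence and noted in the result rather than
  treated as missing data.
* Models that do not grow on the full medium are flagged non-growing; all
  their calls are NA and they join the exclusion report.
* All 20 amino acids are screened; analyses can restrict to a subset, but
  the package does not guess one.

The completeness gate keeps models with genome completeness ≥ 85 %
(inclusive); excluded models are listed with a reason. Screening a
knocked-out template model recovers planted auxotrophy sets with precision
and recall 1.0 — by construction the knockout removes the only synthesis
route, so this is a correctness check of the whole LP path, not a
statistical claim.

## Extracellular peptidase calling

Peptidase genes are called by homology against a scan-sequence database in
the style of the MEROPS peptidase-unit collection: each entry has an
identifier like `S09.075` (family S09, member 075; letters may appear in
the member part, e.g. `S09.A41`), a scan sequence, and the span of its
peptidase unit (catalytic domain).

Every scan sequence (the query) is aligned against every genome protein by
Smith–Waterman with affine gaps (BLOSUM62; gap open 11, extend 1; a gap of
length L costs 11 + L; the unknown residue X scores 0). Raw scores are
converted with Karlin–Altschul statistics, bitscore = (λ·S − ln K)/ln 2 and
E = m·n·2^(−bitscore), with λ = 0.267 and K = 0.041 fixed at the gapped
BLOSUM62 defaults and n the total residue count of the proteome searched —
fixing these makes scores reproducible without a search heuristic. A hit is
retained when all four filters hold in one conjunctive pass:

| filter | threshold | semantics |
|---|---|---|
| E-value | < 0.01 | strict |
| query (scan) coverage | > 85 % | strict |
| bitscore | > 100 | strict |
| peptidase-unit coverage | ≥ 95 % | inclusive |

The strict/inclusive reading mirrors the wording each threshold came with;
boundary behavior is pinned by tests (a hit exactly at bitscore 100 or at
94 % unit coverage is rejected; exactly 95 % unit coverage is kept).

A peptidase gene counts as extracellular when its protein carries a signal
peptide. Signal-peptide prediction is an input annotation, matching the use
of a trained external predictor on real data. For synthetic data the
package uses a documented toy rule (≥ 1 K/R among residues 2–4 and a run of
≥ 8 hydrophobic residues among positions 5–25) — the generator plants
prefixes satisfying it, so the rule is exact ground truth there; it is not
a substitute predictor for real proteomes. Per genome the profile records
gene copies (each retained protein × peptidase hit) and distinct peptidase
identifiers; weighted averages default to copies, since "genes encoding"
suggests copy counting, while peptidase abundances always use presence.

## Community metrics

With per-sample genome abundances *w*, auxotrophy calls, and peptidase
profiles:

* **Auxotrophy abundance** of amino acid *a*: Σ of *w* over genomes
  auxotrophic for *a*.
* **Weighted average auxotrophies**: Σ *w·n* with *n* the per-genome
  auxotrophy count (0–20); similarly for extracellular peptidase gene
  copies.
* **Peptidase abundance** of id *p*: Σ of *w* over genomes carrying at
  least one extracellular homolog of *p* (presence semantics).
* Genomes present in a sample but absent from a profile (below the
  completeness gate, or non-growing) are dropped and weights renormalized
  over profiled genomes; the dropped fraction is attached to every metric
  so heavily-truncated samples are visible. With identical renormalization
  the weighted average equals the sum of the 20 auxotrophy abundances — an
  identity asserted in tests.
* **Bray–Curtis dissimilarity**: 1 − 2Σmin(x,y)/(Σx + Σy) over the union
  of ids; undefined (an error) when both profiles are all-zero, and
  all-zero rows are dropped (with a warning) before building distance
  matrices. Peptidase profile vectors for ordination and screening are the
  per-sample peptidase abundances over all extracellular ids.
* **Range scaling** for heatmap-style output: (v − min)/(max − min), with
  constant vectors mapping to all zeros.
* **Median dissimilarity to a reference set** (e.g. each small-intestine
  sample against all large-intestine samples) uses the usual midpoint
  convention for even counts.

## Statistical layer

* **Kendall tau-b** correlates a per-sample quantity with the ordered
  region rank (duodenum 1, jejunum 2, farthest distance 3, large intestine
  4). Ties on either side use the tau-b correction. Two-sided p-values are
  exact for n ≤ 8 — full enumeration of value permutations, conditional on
  the observed tie pattern — and otherwise use the classical tie-corrected
  normal approximation (identical to `cor.test`'s, which tests cross-check).
* **Wilcoxon tests** use exact enumeration when the pooled (rank-sum) or
  retained (signed-rank) sample size is ≤ 12 without ties, else the
  tie-corrected normal approximation with continuity correction. Zero
  differences are dropped; all-zero difference vectors return p = 1,
  flagged. Midranks are always used; ties are never broken randomly.
* **BH-FDR** is the standard step-up adjustment (`p.adjust`), applied
  jointly across the whole Spearman auxotrophy × peptidase matrix, across
  the per-amino-acid region and group tests, and inside the screen.
* **PCoA** double-centers −½D² and eigendecomposes; coordinates come from
  positive-eigenvalue axes (descending), negative eigenvalues are reported
  unchanged rather than corrected. Asymmetry beyond 10⁻⁹ or a nonzero
  diagonal is an input error.
* **PERMANOVA** is one-way, on squared distances: SS_total =
  (1/N)Σ_{i<j}d²ᵢⱼ, SS_within summed per group, pseudo-F from the usual
  degrees of freedom, R² = SS_among/SS_total. Labels are permuted freely
  (no strata). When the number of distinct label arrangements is ≤ 10,000
  the null distribution is enumerated exactly; otherwise `n_perm` random
  permutations are drawn under a caller-supplied seed and
  p = (1 + #{F* ≥ F})/(1 + n_perm), so p never reaches 0 and the floor at
  the default 999 permutations is 0.001. SS partition and R² are
  cross-checked against an independent implementation in the test suite.
* **Differential peptidase screen.** Peptidases first pass a prevalence
  filter — median relative abundance ≥ 1 % in either group — then each is
  tested (signed-rank when paired, rank-sum otherwise), p-values are
  BH-adjusted, and hits below `alpha` (default 0.001) are flagged with the
  direction of the median difference. Adjusting before thresholding
  follows the stated adjust-everything policy; a `adjust = "none"` flag
  exists because the prose describing the screen is ambiguous on this
  point, and type-I calibration is checked in raw-p mode.

## What the synthetic generator emulates — and what it does not

`make_catalog()` plants, per genome: a 16S gene mutated from a shared
300-nt ancestor at ~5 % divergence (so genomes sit near 90 % pairwise
identity — well below the 97 % mapping threshold, keeping ASV assignment
unambiguous); an independent auxotrophy set (each amino acid with
probability `aux_rate_per_aa`, realized as biosynthesis-reaction knockouts
of a 64-reaction template model that grows on carbon alone); secreted
copies of scan-database entries at `domain_mutation_rate` substitutions per
residue behind a signal prefix; one scrambled decoy domain; and a
completeness drawn from {80, 90, 100} so the 85 % gate always has work to
do. `make_samples()` draws genome weights from a Dirichlet whose
concentration is base·exp(aux_tilt·z_aux + pep_tilt·z_pep), with z the
standardized planted counts, then emits multinomial reads (default 10,000
per sample) over three ASVs per genome at 100 %, 97 % and 95 % identity
(0.65/0.25/0.10 of the genome's reads) — the 95 % ASV is planted
unmappable. Default study designs tilt the three small-intestine regions
toward auxotrophy-rich genomes (aux_tilt 1.5) and the large intestine
toward peptidase-rich genomes (pep_tilt 1.5); the SIBO design removes the
auxotrophy tilt and adds the peptidase tilt in the SIBO group. Everything
is a pure function of (parameters, seed).

Because the tilt acts on the *total* planted counts, the planted direction
of an individual amino acid is emergent: it follows from which genomes
carry it. The validation therefore derives each amino acid's expected
direction from the truth itself — the expected carrier share
Σ_carriers c_i / Σ c_i under each region's concentration vector,
restricted to gate-passing genomes exactly as the pipeline renormalizes —
and asserts recovery only for amino acids whose expected share differs by
at least 0.1 between duodenum and large intestine (an unambiguous planted
effect at 30 samples per region). Note that both tilts enter this
expectation: the large-intestine peptidase tilt also moves amino-acid
carrier shares whenever auxotrophy and peptidase counts co-occur in the
same genomes.

What the generator does **not** emulate: realistic sequence evolution
(mutations are i.i.d. substitutions; no indels in 16S, no chimeras, no
sequencing-error profile), realistic metabolic networks (one linear
biosynthesis route per amino acid, no alternative pathways or peptide
transporters), compositional structure of real gut communities, or a real
signal-peptide model. Passing tests therefore demonstrate that the
pipeline's logic is correct and calibrated — not that its thresholds are
optimal for any particular real dataset.

## Numerical choices and degenerate inputs

* Simplex pivot tolerance 10⁻⁹; Bland's rule for entering and leaving
  variables guarantees termination under degeneracy; finite lower bounds
  are required (upper bounds may be infinite, enabling unbounded
  detection).
* Mapping and screening thresholds are compared inclusively (≥) except
  where the calling contract states strict inequalities (the three strict
  peptidase filters); ties at the maximum mapping identity are compared
  with a 10⁻⁹ slack.
* Constant vectors: Kendall returns a flagged undefined tau; Spearman
  cells with a constant column are NA and excluded from the joint FDR;
  range scaling maps constants to zeros.
* Both-empty profiles make Bray–Curtis undefined (error), and all-zero
  rows are dropped from distance matrices with a warning rather than
  silently imputed.
* Permutation draws always run under an explicit seed with the caller's
  RNG state saved and restored, so pipeline reruns are byte-identical.

## Problem sizes used in validation

The shipped validation uses sizes chosen to exercise every code path in
seconds-to-minutes on one CPU: 200 random ≤ 8-reaction networks for the LP
oracle; 100 genomes for the planted-auxotrophy screen; 30 genomes at 2 %
domain mutation for peptidase recall; a 40-genome catalog with 30 samples
per region (120 samples, 999 permutations) for the end-to-end study; 200
replicates for null-PERMANOVA uniformity; 1,000 replicates (10 vs 10
samples) for the screen's type-I error, expected to land in [0.03, 0.07]
at nominal 0.05 given the discreteness of rank tests.

## Known limitations

* The FBA stage answers a binary growth/no-growth question; it does not do
  flux-variability analysis, parsimonious FBA, or medium inference, and
  auxotrophy calls inherit every limitation of the input models.
* The peptidase caller is an explicit all-vs-all aligner with fixed
  Karlin–Altschul parameters — reproducible, but not a BLAST replacement
  at scale, and its E-values are approximations tied to those constants.
* Equal-split tie apportionment biases toward genomes with many close
  relatives in the catalog; `drop_ambiguous` trades that bias for lost
  reads.
* One-way PERMANOVA only: no strata, no multi-factor designs, no
  dispersion (PERMDISP) test, so location and dispersion effects are
  confounded as in any plain PERMANOVA.
* The SBML importer covers the core + fbc subset needed for these models
  (species, stoichiometry, parameterized bounds, objective); exotic SBML
  features (rules, kinetic laws as bounds) are ignored.
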
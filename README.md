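# auxopep

Comparative profiling of **amino-acid auxotrophies** and **extracellular
peptidase gene repertoires** in gut microbiome communities, from 16S
amplicon data and a reference genome catalog.

## The scientific problem

Gut bacteria differ widely in their biosynthetic capacity: many cannot
synthesize one or more of the 20 proteinogenic amino acids (they are
*auxotrophic*) and must acquire them from their environment — from host
diet, or by hydrolyzing peptides with secreted (extracellular) peptidases.
Along the intestinal tract the nutrient landscape changes sharply, so the
balance between auxotrophic genotypes and peptidase-carrying genotypes is
expected to shift between the small intestine, the large intestine, and
dysbiotic states such as small intestinal bacterial overgrowth (SIBO).

`auxopep` implements the full comparative analysis as a tested, reusable R
pipeline:

1. **ASV → genome mapping.** Amplicon sequence variants are aligned
   semi-globally against the 16S genes of a reference catalog (both
   orientations); hits need ≥ 97 % identity and ≥ 95 % query coverage, and
   only hits at an ASV's maximum identity are kept. Read counts are split
   equally across tied genomes and normalized to per-sample relative
   abundances.
2. **Auxotrophy prediction by flux-balance analysis (FBA).** For each
   genome-scale metabolic model (completeness ≥ 85 % gate), growth is the
   solution of the linear program max *v*<sub>biomass</sub> subject to
   *S v* = 0, lb ≤ *v* ≤ ub, with exchange lower bounds set from the growth
   medium. A genome is auxotrophic for amino acid *a* when it grows on the
   full medium but not after removing *a*'s exchange from the medium
   (growth < 10⁻⁶). The LP is solved by an in-package two-phase simplex.
3. **Extracellular peptidase calling.** Every MEROPS-style scan sequence is
   Smith–Waterman-aligned (BLOSUM62, gap open 11 / extend 1) against every
   protein; hits are kept when E-value < 0.01, query coverage > 85 %,
   bitscore > 100 and peptidase-unit coverage ≥ 95 % (Karlin–Altschul
   statistics with λ = 0.267, K = 0.041), then restricted to proteins
   carrying a signal peptide.
4. **Community metrics.** Per sample: *auxotrophy abundance* (summed
   relative abundance of genomes auxotrophic for an amino acid), the
   abundance-weighted average number of auxotrophies (0–20) and of
   extracellular peptidase genes, peptidase abundances (carrier share per
   peptidase species), Bray–Curtis dissimilarities
   (1 − 2Σmin/(Σx + Σy)) and range scaling.
5. **Statistics.** Kendall tau-b against the ordered regions
   duodenum (1) → jejunum (2) → farthest distance (3) → large intestine (4);
   Wilcoxon rank-sum and signed-rank tests (exact by enumeration for small
   samples); Benjamini–Hochberg FDR; Spearman auxotrophy × peptidase
   correlation matrices with joint FDR; PCoA; one-way PERMANOVA with the
   add-one permutation convention; a differential-peptidase screen with a
   1 %-median prevalence filter.
6. **Synthetic data with planted truth.** A generator emits a complete
   study — catalog, knockout models, scan database, signal annotations,
   ASVs at identities straddling the mapping threshold, and
   Dirichlet-multinomial communities tilted toward auxotrophy-rich or
   peptidase-rich genomes per region/group — so every stage can be scored
   against known ground truth.

## Worked example

```r
library(auxopep)

# a synthetic study: 12 genomes, 5 samples per gut region
bundle  <- make_catalog(12, aux_rate_per_aa = 0.2, pep_gene_rate = 0.4, seed = 7)
samples <- make_samples(bundle, default_study_design(n_per_region = 5), seed = 8)

# map ASVs to the catalog and derive genome relative abundances
hits <- map_asvs(samples$asvs, bundle$catalog)     # >= 97% identity, best hits
sa   <- assign_abundance(samples$asvs, hits, samples$metadata)

# leave-one-out FBA auxotrophy screen (completeness gate 85%)
aux <- screen_catalog(bundle$models, bundle$medium)
aux
#> <auxotrophy_profile> 5 genomes profiled, 7 excluded; median auxotrophies: 4

# extracellular peptidase calling
pep_hits <- call_peptidases(bundle$catalog, bundle$scan_db)
pep <- flag_extracellular(pep_hits, bundle$signal_table,
                          genomes = names(bundle$catalog$genomes))
pep
#> <peptidase_profile> 12 genomes; 39 extracellular peptidase gene hits; 8 distinct peptidase ids

# community metrics
metrics <- community_metrics(sa, aux, pep)
head(metrics[, c("sample_id", "region", "weighted_avg_auxotrophies",
                 "weighted_avg_peptidases")], 4)
#>   sample_id   region weighted_avg_auxotrophies weighted_avg_peptidases
#> 1      S001 duodenum                  6.780533                2.823732
#> 2      S002 duodenum                  6.627772                2.934730
#> 3      S003 duodenum                  6.772358                2.707944
#> 4      S004 duodenum                  6.406524                2.798173

# does the weighted auxotrophy average fall along the intestinal tract?
kendall_ordered(metrics$weighted_avg_auxotrophies,
                region_rank(metrics$region))
#> <test> tau = -0.6279  p = 0.0003618

# do peptidase profiles separate the regions?
pm <- peptidase_abundance_matrix(sa, pep)
permanova(bray_curtis_matrix(pm), metrics$region, n_perm = 999, seed = 1)
#> <test> pseudo-F = 71.48  p = 0.001
```

The negative Kendall tau says the community-average number of auxotrophies
is highest in the duodenum and falls toward the large intestine — the
direction planted by `default_study_design()`, which tilts small-intestine
communities toward auxotrophy-rich genomes. The PERMANOVA p of 0.001 (the
floor at 999 permutations) says the regional peptidase profiles are
cleanly separated.

The same analysis runs end to end from files on disk:

```r
write_dataset(bundle, samples, "dataset")
run_pipeline(pipeline_config("dataset", "results", seed = 1))
```

or from a shell via the bundled CLI
(`Rscript inst/cli/auxopep.R run-all --input dataset --outdir results`).

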
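Package: auxopep
Title: Auxotrophy and Extracellular Peptidase Profiling of Gut Microbiome
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative profiling of predicted amino-acid auxotrophies and
    extracellular peptidase gene repertoires across gut microbiome samples.
    Maps 16S amplicon sequence variants (ASVs) to a reference genome catalog,
    predicts amino-acid auxotrophies by leave-one-out flux-balance analysis
    on genome-scale metabolic models, calls secreted peptidase genes by
    homology against a MEROPS-style scan-sequence database, and derives
    abundance-weighted community metrics together with the rank-based
    statistical layer (Kendall ordered correlation, Wilcoxon tests,
    Benjamini-Hochberg FDR, PCoA, PERMANOVA, Bray-Curtis dissimilarities).
    Includes a synthetic-data generator with planted ground truth so the
    whole pipeline can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
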
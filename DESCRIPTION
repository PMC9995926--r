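Package: coexmeth
Title: Bipartite mRNA-DNA Methylation Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired RNA-seq expression and array DNA
    methylation in small two-group cohorts. Provides differential screening of
    both molecular layers (median-of-ratios normalization, FPKM, moderated
    two-group t tests with empirical-Bayes variance shrinkage, Benjamini-
    Hochberg adjustment), construction of a bipartite Pearson co-expression
    network between differentially methylated positions and differential
    mRNAs, degree-based hub screening, overlap and Fisher-exact gene-set
    enrichment analyses, two-way hierarchical clustering orderings, and
    2^-ddCt relative quantification for qPCR validation. Includes a synthetic
    paired-cohort generator with planted differential and hub structure and a
    truth-recovery report for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
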
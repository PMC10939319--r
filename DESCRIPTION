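Package: thermosex
Title: Temperature-Induced Sex Reversal Statistics and Transcriptome Screens
        for Nile Tilapia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for high-temperature masculinization experiments
    in Nile tilapia (Oreochromis niloticus). Computes family-level sex-reversal
    statistics (male ratios, inversion rate IR, relative survival rate RSR,
    exact Fisher and binomial tests, logistic-regression group comparisons
    with compact letter displays, Spearman correlations) and runs a paired
    treated/control transcriptome inference chain: counts-per-million
    normalization, precision-weighted linear models with empirical-Bayes
    moderated t-statistics, exon-level differential-splicing tests with Simes
    aggregation, per-family fold-change correlation against the reversal-rate
    phenotype, soft-threshold co-expression networks around seed genes,
    DEG/DSG/Corr evidence integration with Venn partitions, and hypergeometric
    gene-set over-representation with majority-vote identifier resolution and
    ortholog-based annotation augmentation. Includes a synthetic-data module
    emulating the 6-family x 2-treatment x 2-tissue x 2-stage study design
    with planted ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
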
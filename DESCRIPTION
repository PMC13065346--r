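Package: miRland
Title: Landscape Analysis of Extracellular-Vesicle miRNA Count Data
Version: 0.1.0
Authors@R:
    person("miRland", "Maintainers", email = "mirland@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for small-RNA sequencing count
    matrices from extracellular-vesicle (EV) preparations profiled across
    several parent cell types. Harmonizes miRNA count files produced by
    different alignment pipelines (arm-suffix resolution, zero-filling),
    computes counts-per-million and median-of-ratios normalization with PCA,
    partitions detected miRNAs by the subset of EV subtypes expressing them,
    runs all-pairwise negative-binomial Wald differential expression with
    Benjamini-Hochberg FDR control, computes the tissue-specificity index
    tau, and applies a three-criteria (abundance, upregulation, enrichment)
    integrative filter to call subtype-specific key miRNAs. Includes a
    negative-binomial count simulator with known ground truth emulating a
    four-group EV study design, and an assumption-driven router for grouped
    numeric comparisons (ANOVA/Tukey, Welch ANOVA/Dunnett T3,
    Kruskal-Wallis/Dunn, and two-sample t-test variants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
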
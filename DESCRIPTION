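Package: ravburden
Title: Ultra-Rare Variant and Structural Variant Burden Analysis for
    Case-Control Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for case-control whole-genome
    sequencing burden analysis of ultra-rare single-nucleotide variants,
    indels and structural variants. Provides genotype-, variant- and
    sample-level quality control (exact Hardy-Weinberg filtering,
    differential missingness, relatedness pruning, ultra-rare-variant
    outlier pruning, blacklist filtering of structural variants),
    frequency- and consequence-class variant classification against
    constraint tracks and genomic annotations (including topologically
    associating domain boundaries), interval arithmetic for reciprocal
    overlap, callset concordance and population-database absence,
    covariate-adjusted logistic burden models with one-sided tests,
    permutation empirical p-values and Benjamini-Hochberg false discovery
    rate control, single-variant association with genomic-control
    inflation, analytic case-control power under the additive liability
    model, Fisher exact contrasts, and MAF/LD-stratified GREML
    heritability estimation with liability-scale transformation. A
    synthetic-cohort generator with known embedded effects supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    S4Vectors,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
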
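Package: envchip
Title: Design and Analysis of Environmental Functional-Gene Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for thermodynamics-driven design and downstream analysis
    of functional-gene expression microarrays for environmental microbial
    communities. Implements nearest-neighbor melting temperatures with a
    linear mismatch-Tm penalty, probe enumeration with hairpin/repeat/Tm
    screens and a 15 degree-Celsius uniqueness rule against nontarget and
    rRNA sequence sets, ungapped cross-hybridization screening with
    Karlin-Altschul E-values and taxonomic hit classification, the microarray
    expression pipeline (quantile normalization, lowest-5% background,
    background+3SD expression calls, seasonal freshwater-baseline log2
    ratios, differential selection, phylum and family rollups, Spearman
    correlations, one-way ANOVA filtering), complete-linkage correlation
    clustering with Newick/CDT export, and seeded generators for
    taxonomically structured synthetic communities and intensity matrices
    with planted truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
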
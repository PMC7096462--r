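Package: regenSig
Title: Cross-Contrast Regeneration Signatures from Multi-Mutant RNA-Seq Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression and specificity analysis for panels of
    wildtype-versus-mutant RNA-seq contrasts, built around the seven-mutant
    SMN-complex design (smn1 and gemin2-7 zebrafish lines). Implements a
    negative-binomial Wald test with median-of-ratios normalization and
    gene-wise moment dispersion estimates, a cross-contrast rule that labels
    genes up- or down-regulated specifically in regeneration-deficient
    mutants, hierarchical clustering of contrasts on log2 fold-change
    profiles, Fisher-exact over-representation of the resulting gene lists
    with contrast-specific enrichment labeling, and a seeded
    negative-binomial simulator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RNASeq, DifferentialExpression, GeneSetEnrichment, Clustering
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'de.R'
    'classify.R'
    'cluster.R'
    'enrichment.R'
    'io.R'
    'simulate.R'
    'pipeline.R'
    'show-methods.R'
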
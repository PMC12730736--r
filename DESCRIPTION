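Package: ModifierNet
Title: Network-Based Prioritization of Genetic Modifiers in Two-Subject Rare-Disease Comparisons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative systems-biology toolkit for identifying candidate
    genetic modifiers when only two subjects (e.g., phenotypically discordant
    siblings carrying the same primary lesion) are available. Implements a
    variant annotation filter cascade (population allele frequency, CADD
    deleteriousness, pLI constraint), subject-specific protein-protein
    interaction networks with component decomposition, a negative-binomial Wald
    test for two-group RNA-seq comparisons, sparse PLS-DA with recursive
    feature elimination, functional-interaction networks with linker genes,
    hypergeometric over-representation analysis with weighted set-cover
    redundancy reduction, preranked GSEA, and phenotype-ontology virtual gene
    panels intersected with the expression networks to shortlist candidate
    modifiers. A fully seeded synthetic-data generator with planted
    ground-truth modifiers makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mixOmics,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ModifierNet-package.R'
    'synthio.R'
    'io.R'
    'variants.R'
    'fixtures.R'
    'netbuild.R'
    'rnaseq.R'
    'mvsel.R'
    'enrich.R'
    'integrate.R'
    'recovery.R'
    'pipeline.R'
biocViews: Software, Network, DifferentialExpression, VariantAnnotation,
    GeneSetEnrichment, SystemsBiology
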
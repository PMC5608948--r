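Package: popDiverge
Title: Inter-Population Divergence Analysis for Multi-Omics Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies inter-population differentiation across genetic and
    quantitative omics platforms in multi-ethnic cohorts. Implements per-variant
    Wright's F_ST across k populations (SNPs and one-vs-rest HLA classical
    alleles) with empirical p-values against a genome-wide null, a binomial
    window scan for contiguous regions enriched in high-F_ST variants,
    covariate-adjusted three-group ANOVA contrasts with least-squares means and
    fold changes, correlation-based tagging of lipid species, genotype and
    matrix quality-control filters (missingness, Hardy-Weinberg exact test,
    call rate), and principal component ordination. A synthetic three-population
    cohort generator (Balding-Nichols allele frequencies, Dirichlet multi-allelic
    loci, block-correlated log2 lipid concentrations with planted group shifts)
    makes the full pipeline testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
biocViews: Genetics, SNP, QualityControl, PrincipalComponent, Lipidomics,
    DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
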
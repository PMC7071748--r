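Package: aspupipe
Title: Combined-Phenotype GWAS with the Adaptive Sum of Powered Scores Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end combined-phenotype genome-wide association pipeline
    for correlated quantitative traits, built around the adaptive sum of
    powered scores (aSPU) Monte-Carlo test. Provides univariate additive-model
    association with covariate adjustment and phenotype/variant quality
    control, fixed-effect inverse-variance-weighted meta-analysis across
    analytic subgroups with Cochran's Q heterogeneity and genomic-control
    diagnostics, estimation of the null z-score correlation matrix, SPU(gamma)
    and adaptive aSPU p-values with a staged Monte-Carlo escalation schedule,
    iterative conditional analysis to enumerate independent association
    signals, locus definition and LD-proxy annotation, and generalization
    testing of previously reported regions. A multi-subgroup genotype and
    phenotype simulator with known ground truth (Hardy-Weinberg sampling,
    block-autoregressive linkage disequilibrium, subgroup-specific allele
    frequencies and correlated trait residuals) makes every stage testable
    without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
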
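Package: longvc
Title: Constrained Multivariate Variance-Component Association for
    Longitudinal Traits in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measured-genotype association testing for quantitative traits
    with repeated measurements in extended pedigrees. Implements the
    constrained multivariate likelihood-ratio test in which a variant's
    mean effect is forced equal across all time points, together with the
    unconstrained per-time-point test and the univariate test on the
    time-averaged trait, all within a maximum-likelihood
    variance-component framework using the pedigree kinship matrix.
    Also provides a gene-centric variance-component test based on a
    region-local empirical genetic relationship matrix with a
    boundary-mixture null, a recursive kinship-matrix computation with a
    Monte-Carlo gene-dropping cross-check, and a synthetic family-study
    generator (gene-dropped genotypes, longitudinal polygenic traits)
    for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'vc-fit.R'
    'vc-api.R'
    'assoc.R'
    'genotypes.R'
    'kernel.R'
    'pedigree.R'
    'phenotypes.R'
    'sim.R'
    'study.R'
    'zzz.R'
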
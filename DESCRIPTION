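Package: epiprs
Title: Polygenic Risk Prediction from Imputed Epigenomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an epigenome-aware polygenic risk scoring workflow:
    construction of phased diploid personal genome sequences from a reference
    FASTA and phased SNV genotypes, windowed imputation of epigenomic feature
    tracks through a pluggable sequence-to-feature extractor, per-bin local
    principal component reduction across individuals, GWAS-driven selection of
    linkage-disequilibrium blocks, and gradient-boosted risk models with
    linear-baseline comparisons. Ships RegPheno-style regulatory phenotype
    simulation: phased synthetic cohorts with a controllable rare-variant
    spectrum and binary phenotypes drawn from a four-component liability model
    (epigenetic, direct, environmental and interaction effects), plus feature
    and bin importance analyses with annotation-overlap enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost,
    glmnet,
    Biostrings,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
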
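Package: layres
Title: Resilience Indicators, Genetic Parameters and Mixed-Model GWAS for
    Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying resilience of laying hens from
    longitudinal egg-production records and for mapping its genetic basis.
    Computes per-hen deviations of weekly egg production from the batch mean
    curve and summarises them into three resilience indicators (log-variance,
    skewness and lag-one autocorrelation of deviations), applies SNP-array
    quality control, builds pedigree (A) and VanRaden genomic (G)
    relationship matrices, estimates variance components and heritability
    with a REML animal model, and runs a single-SNP mixed-model genome-wide
    association study with a fixed variance ratio, genomic-control inflation
    factors and Storey q-value FDR correction.  A configurable synthetic
    batch generator (pedigree, gene-dropped genotypes, natural-antibody
    titers, daily egg laying with disturbances and culling) makes every
    stage of the pipeline testable without access to proprietary breeding
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
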
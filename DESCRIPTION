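Package: tractpop
Title: Ancestry-Stratified Population Genomics for Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ancestry-aware population-genomic and complex-trait
    analysis of admixed cohorts. Provides interval algebra linking runs of
    homozygosity (ROH) and identity-by-descent (IBD) segments to haplotype-
    level local-ancestry tracts, inference of ancestry-specific effective
    population size trajectories from IBD length spectra under a Poisson
    coalescent mixture model, derived-allele mutation-burden summaries
    polarized by ancestral alleles, and a genotype-phenotype modelling stage
    (phenotype quality control, inverse-normal and 2-SD transforms, GRM
    construction, association scans, clump-and-threshold polygenic scores,
    and a linear mixed model with kinship and locality random effects).
    A synthetic-cohort generator with known ground truth (pulse-admixture
    tracts, bottlenecked allele-frequency spectra, model-consistent IBD and
    implanted ROH, structured phenotypes) makes every stage testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
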
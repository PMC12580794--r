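Package: clonemap
Title: Multisite Tumor Clonality, Phylogeny, and Metastatic Seeding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the clonal architecture of multisite (multi-region
    or rapid-autopsy) tumor cohorts from somatic variant calls, absolute
    copy-number segments, and per-sample purity/ploidy estimates. Computes
    cancer cell fractions (CCF) with maximum-likelihood multiplicity
    estimation, classifies mutations and copy-number events by presence and
    clonality across metastatic sites, clusters mutations into clones,
    reconstructs clone phylogenies under the pigeonhole and infinite-sites
    constraints, infers metastatic seeding and migration patterns, quantifies
    the illusion of clonality and per-sample detection rates, extrapolates
    mutation discovery with a species-accumulation model, and tests
    cross-sample LOH overlap with a permutation null. A synthetic multisite
    cohort generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
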
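Package: ovitherm
Title: Heat-Stress Phenotyping and Mixed-Model Association Genetics for
    Sheep SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying heat tolerance in small ruminants and
    mapping its genetic basis from medium-density SNP chip data. Computes
    the temperature-humidity index (THI) from meteorological records and a
    0-5 animal heat-tolerance index (AHTI) from paired rest/stress
    physiological measurements (rectal and ear temperature, respiration
    rate, tidal volume, metabolic rate). Provides SNP quality control
    (minor allele frequency, call rate, exact Hardy-Weinberg test),
    multilocus diversity statistics (Nei's unbiased gene diversity, the
    index of association and its standardized form), Weir-Cockerham Fst
    with neighbor-joining trees, population-structure inference (PCA,
    discriminant analysis of principal components with BIC cluster
    selection, least-squares admixture with masked cross-entropy selection
    of K), efficient mixed-model association (EMMA/P3D) with vanRaden
    genomic kinship, and positional SNP-to-gene annotation with a
    hypergeometric over-representation test. A seeded synthetic-data
    generator produces admixed genotypes and heat-stress physiology with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    MASS,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
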